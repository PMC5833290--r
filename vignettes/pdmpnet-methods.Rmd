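---
title: "From Boolean topologies to exact stochastic promoter dynamics: the pdmpnet model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From Boolean topologies to exact stochastic promoter dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The modelling problem

Network-inference pipelines typically deliver a *Boolean-level* description
of a gene-regulatory network: a set of genes and signals, and signed
(activating/repressing) directed edges. Such a description says nothing
about promoter occupancy kinetics, molecular noise, or the time scales of
gene-state switching, yet those are exactly the ingredients that shape
single-cell heterogeneity. `pdmpnet` compiles a Boolean topology into a
mechanistic reaction network with explicit promoter architecture and
simulates it exactly, so that questions about switching regimes, attractor
structure and transition dynamics can be asked of a topology that was
inferred from population data.

The packaged application is the naive-pluripotency program of mouse
embryonic stem cells: twelve transcription factors (TFs) downstream of the
three culture signals LIF, CH (GSK3 inhibition) and PD (MEK inhibition),
after the minimal program identified by Dunn *et al.* (2014).

## Molecular logic

Every gene $i$ carries $N$ identical promoter sites. Each regulator
$P_j$ in the gene's regulator set $S_i$ binds any free site independently
(parallel binding) at rate $N k_{on} \Omega^{-1}$ per free molecule and per
free site, and each bound copy unbinds at rate $k_{off}$. One rule set
applies to every gene:

* regulated by activators only: **ON** iff all $N$ sites are
  activator-bound, else **OFF**;
* regulated by repressors only: **OFF** iff all $N$ sites are
  repressor-bound, else **ON**;
* regulated by both: **ON** when fully activator-bound, **OFF** when fully
  repressor-bound, **MEDIUM** otherwise;
* unregulated: constitutively **ON**.

The production rate of the gene's TF is $\Omega\alpha_{max}$,
$\Omega\alpha_m$ or $0$ for ON / MEDIUM / OFF, and every TF degrades at
rate $\gamma$ (free copies only; promoter-bound copies are distinct species
and protected). Signals are constant species: present means density 1
(count $\Omega$), absent means 0.

## Non-dimensionalization

Time is measured in units of $1/\gamma$ and concentration in units of
$\alpha_{max}/\gamma$, so $\gamma = \alpha_{max} = 1$, densities live in
$(0,1)$, and four free parameters remain:

| parameter | meaning | default | units |
|---|---|---|---|
| `n_sites` (N) | promoter sites per gene | 2 | — |
| `k_on` | per-site binding rate constant | 16 | $\gamma$ |
| `k_off` | per-bound-copy unbinding rate | 1.5 | $\gamma$ |
| `alpha_m` | MEDIUM production rate | 0.01 | $\alpha_{max}$ |
| `omega` | population scale (SSA only) | $10^4$ | molecules |

The defaults are the *intermediate* switching regime; `regime_params()`
also provides the *slow* (3.2, 0.2, 0.02) and *fast* (102, 10, 0.005)
regimes, three representative points in the low-cost valley of the
checkerboard fit described below. For stable pluripotency factors
($\gamma \approx 1/8\,h^{-1}$) one non-dimensional time unit is about 8
hours (`to_physical_time()`).

## Exact simulation as a piecewise-deterministic Markov process

Between promoter events the TF densities obey $\dot x_i = \alpha_i - x_i$,
solved in closed form by `flow()`. Promoter events are a competing-risks
jump process whose channel hazards are affine in the densities; since each
density relaxes exponentially, every channel hazard has the form
$c_0 + c_1 e^{-t}$ and the total hazard is
$\Lambda(t) = a + c\,e^{-t}$ with integrated hazard

$$H(t) = a t + c\,(1 - e^{-t}).$$

Waiting times are drawn by exact inversion of $H$ against a unit-mean
exponential deviate: in closed form through the principal Lambert-W branch
($t^* = d + W((c/a)e^{-d})$, $d = (e-c)/a$), with bracketed monotone
root-finding as fallback near the branch point or under over/underflow. No
survival function is integrated numerically, so the sampler is exact up to
floating-point tolerance (the suite checks agreement with quadrature to
1e-10 and distributional correctness by Kolmogorov–Smirnov tests). The
compiled engine uses a bracketed Newton iteration on $H$, which is the same
root to ~1e-14; the R-level `sample_event_time()` exposes both the Lambert
and the bisection routes and the tests require them to agree.

Promoter events do not displace densities: binding sequestration is an
$O(1/\Omega)$ effect that the PDMP neglects, and exactly the discrepancy
that the individual-based validation (below) bounds.

The telegraph fixture (one gene, one site, one constant activator) is the
analytic anchor: its stationary PDMP density is Beta($k_{on}$, $k_{off}$),
and the suite requires goodness of fit at level 0.01 with $10^4$ paths.

## Individual-based validation

`simulate_ssa()` runs the *same* reaction set (binding, unbinding,
production, degradation at integer copy numbers) with Gillespie's direct
method, propensities maintained incrementally. Because the PDMP error is
$O(\Omega^{-1})$, SSA marginals converge to PDMP marginals as $\Omega$
grows; the suite checks monotone convergence on the telegraph fixture and,
at the working scale $\Omega = 10^4$, per-TF Jensen–Shannon divergence
below 0.05 on the full mESC network. The SSA is roughly three orders of
magnitude slower, which is why the PDMP engine is the workhorse for
parameter sweeps.

## Checkerboard parameter inference

Rate parameters are inferred by matching binarized stationary expression to
a binary benchmark ("checkerboard") of 12 TFs under the five
self-renewal-permissive cultures (LIF+2i, 2i, LIF+CH, LIF+PD, LIF). For a
parameter set, $10^3$ PDMP paths per condition are run to stationarity
(burn-in 50 time units, i.e. ~50 TF lifetimes), mean densities are
binarized with a uniform threshold $\eta$ ("expressed" means strictly
greater), and the Hamming distance to the benchmark is minimized over
$\eta$. Because the distance is piecewise constant in $\eta$, the default
grid is exhaustive: all midpoints between consecutive sorted values plus
flanking candidates; ties break toward the smallest $\eta$.
`sweep_hamming()` scans a parameter grid (default ~200 points anchored at
the three named regimes), checkpointing rows so interrupted sweeps resume
deterministically.

## Ensemble analyses

* **Marginals and transition times.** Histograms use 50 uniform bins on
  $[0, 1.02]$ shared between compared distributions. The Jensen–Shannon
  divergence is computed base 2 (range $[0,1]$); the *divergence*, not its
  square root, is thresholded at 0.3 to define transition times — the
  first snapshot at which all 12 TF marginals are within threshold of
  their final stationary marginals. Both conventions are available
  (`analysis_config(use_distance = )`), and the qualitative orderings
  reported by the tests are stable for 25/50/100 bins. Snapshots default
  to a 0.25-time-unit cadence over $(0, 30)$.
* **Signal-switch experiments.** `run_transition()` equilibrates under the
  first condition (burn-in 50), switches signals instantaneously, and
  records snapshots. TF copies bound to a withdrawn signal remain bound
  until they unbind — withdrawal is not an instantaneous promoter reset.
* **Attractor landscapes.** PCA is fitted on the mean-centered reference
  ensemble only (no per-gene scaling: all densities share one scale);
  other ensembles are projected with the reference centering/loadings and
  binned on a shared grid. The "occupied area" proxy counts grid cells
  above 1% of the reference density maximum.
* **Correlations.** Plain Pearson correlations across paths; zero-variance
  genes yield `NA` rather than an error.

## Randomness and reproducibility

The engines never touch R's global RNG. Each path draws from its own
xoshiro256++ stream spawned by splitmix64 from (seed, path index), so
ensembles are reproducible bit-for-bit, independent of execution order,
and insensitive to surrounding R code. Every file-writing entry point
emits a JSON manifest (parameters, condition, horizon, seed, package
version) sufficient to reproduce its outputs exactly; the seed is
mandatory in run configurations.

## The packaged mESC fixture and its provenance

The network topology and the 12×5 benchmark matrix are *reconstructions*
of the Dunn *et al.* (2014) minimal program and its discretized expression
data. The anchored facts — twelve genes and the LIF/CH/PD inputs; LIF
activating Stat3; PD inhibiting MEK/ERK; CH feeding Tfcp2l1; Nanog
regulated by Klf2, Sox2 and MEK/ERK; exactly Tfcp2l1, Esrrb, Nanog and
Oct4 under mixed activation/repression — are honored exactly. Edges and
benchmark cells not fixed by those anchors were curated from the primary
mESC literature, and both files carry provenance headers. They are data,
not code: correcting a cell or an edge requires no code change.

This matters for interpretation. Analyses that depend only on the model
class (exact sampling, the Beta stationary law, PDMP-vs-SSA agreement,
threshold optimization, metric properties) are independent of the
transcription. Analyses that depend on fine fixture details — the exact
minimal Hamming distance, the N = 1 versus N ≥ 2 gap, which conditions
silence the Nanog/Oct4/Sox2 triad — can shift under an alternative curation
of the unanchored cells; with the packaged reconstruction the optimized
distance stabilizes at 2 with the same two mismatching cells across seeds
and regimes, and under PD (MEK/ERK silenced, hence no active repressor in
this edge set) the Oct4/Sall4/Sox2 positive loops can self-ignite from the
MEDIUM production leak, keeping the triad partially expressed. The
acceptance suite asserts the stronger literature-derived expectations and
deliberately leaves them red where the reconstruction does not meet them.

## What the synthetic fixtures do and do not show

The constitutive, telegraph and toggle fixtures are generated in code and
have closed-form or structural oracles; they validate the engines, not
biology. Passing those tests shows the samplers draw from the exact law of
the specified reaction systems. It does not show that real promoters have
$N$ identical parallel-binding sites, that one rule set fits every gene, or
that mESC culture signals act as binary inputs — those are modelling
assumptions inherited from the Boolean abstraction.

## Numerical choices

* Burn-in 50 time units for stationarity (checked in development by
  requiring JSD < 0.05 between ensemble marginals at burn/2 and burn);
  sweeps use a 30-unit horizon with 300 paths per condition per point to
  keep a ~200-point sweep in minutes.
* Waiting-time inversion tolerance 1e-12 (closed form verified against
  the integrated hazard; falls back to bisection otherwise).
* Default initial condition: all promoters unbound, all densities 0.
* Exact threshold ties in binarization count as "not expressed";
  threshold ties in the $\eta$ scan break toward the smaller $\eta$.
* Degenerate inputs: genes without regulators are constitutively ON;
  empty ensembles, mismatched bins/labels and out-of-range thresholds are
  contract errors, while zero-variance correlations are `NA` markers.

## Known limitations

* The fixture transcription uncertainty described above.
* The PDMP neglects demographic noise entirely; at small $\Omega$
  (≲ a few hundred) use the SSA engine.
* The direct-method SSA is adequate at 12 genes but has no dependency-graph
  optimizations; very large networks would need them.
* Landscape densities use plain binning, adequate for occupied-area
  comparisons but not a substitute for a smoothed density estimate in
  figures.
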