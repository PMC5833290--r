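// Exact simulation engines for promoter-architecture gene networks.
//
// PDMP engine: TF densities follow dx/dt = alpha - gamma*x between promoter
// events; binding/unbinding hazards therefore have the form
// const + trans*exp(-gamma*t), the total integrated hazard is available in
// closed form, and waiting times are generated by exact inversion (no
// numerical quadrature of survival functions).
//
// SSA engine: Gillespie direct method on the full individual-based reaction
// set (binding, unbinding, production, degradation) at integer copy-number
// resolution, with incrementally maintained propensities.
//
// Both engines draw from per-path xoshiro256++ streams spawned by splitmix64
// from (seed, path index), so ensembles are reproducible and independent of
// execution order; R's RNG state is never touched.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---------- RNG ----------
static inline uint64_t splitmix64(uint64_t &s) {
  uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoshiro {
  uint64_t s[4];
  Xoshiro(uint64_t seed, uint64_t stream) {
    uint64_t sm = seed ^ (0xD2B74407B1CE6E93ULL * (stream + 1ULL));
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(sm);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return r;
  }
  inline double unif() {  // strictly inside (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double expo() { return -std::log(unif()); }
};

// ---------- network tables ----------
struct Net {
  int nG, nS, nSlots, N;
  double kon, koff, alpha_m, alpha_max, gamma;
  std::vector<int> slot_gene, slot_reg, slot_sign, has_act, has_rep;
  std::vector< std::vector<int> > slots_of_gene;      // slots targeting gene g
  std::vector< std::vector<int> > slots_of_reg_gene;  // slots whose regulator is gene r
};

static Net parse_net(const List &L) {
  Net n;
  n.nG = as<int>(L["n_genes"]);
  n.nS = as<int>(L["n_signals"]);
  n.N = as<int>(L["n_sites"]);
  n.kon = as<double>(L["k_on"]);
  n.koff = as<double>(L["k_off"]);
  n.alpha_m = as<double>(L["alpha_m"]);
  n.alpha_max = as<double>(L["alpha_max"]);
  n.gamma = as<double>(L["gamma"]);
  n.slot_gene = as< std::vector<int> >(L["slot_gene"]);
  n.slot_reg = as< std::vector<int> >(L["slot_reg"]);
  n.slot_sign = as< std::vector<int> >(L["slot_sign"]);
  n.has_act = as< std::vector<int> >(L["has_act"]);
  n.has_rep = as< std::vector<int> >(L["has_rep"]);
  n.nSlots = (int)n.slot_gene.size();
  n.slots_of_gene.assign(n.nG, std::vector<int>());
  n.slots_of_reg_gene.assign(n.nG, std::vector<int>());
  for (int s = 0; s < n.nSlots; ++s) {
    n.slots_of_gene[n.slot_gene[s]].push_back(s);
    if (n.slot_reg[s] < n.nG) n.slots_of_reg_gene[n.slot_reg[s]].push_back(s);
  }
  return n;
}

static inline double gene_alpha(const Net &net, int g, int bact, int brep) {
  if (!net.has_act[g] && !net.has_rep[g]) return net.alpha_max;  // constitutive
  if (net.has_act[g] && !net.has_rep[g])
    return bact == net.N ? net.alpha_max : 0.0;
  if (!net.has_act[g])
    return brep == net.N ? 0.0 : net.alpha_max;
  if (bact == net.N) return net.alpha_max;
  if (brep == net.N) return 0.0;
  return net.alpha_m;
}

// ---------- waiting-time inversion ----------
// Solves a*t + (c/gamma)*(1 - exp(-gamma*t)) = e for t >= 0.
// Returns +Inf when the cumulative hazard saturates below e.
static double solve_tau(double a, double c, double e, double gamma) {
  double a2 = a / gamma, c2 = c / gamma;
  if (a2 <= 1e-300) {
    if (c2 <= e) return R_PosInf;
    return -log1p(-e / c2) / gamma;
  }
  double lo = 0.0, hi = (e - std::min(0.0, c2)) / a2 + 1e-9;
  double u = e / (a2 + std::max(c2, 0.0));  // lower bound on the root
  if (!(u > lo && u < hi)) u = 0.5 * hi;
  for (int it = 0; it < 80; ++it) {
    double em = std::exp(-u);
    double f = a2 * u + c2 * (1.0 - em) - e;
    if (f > 0) hi = u; else lo = u;
    double fp = a2 + c2 * em;
    double un = (fp > 0) ? u - f / fp : 0.5 * (lo + hi);
    if (!(un > lo && un < hi)) un = 0.5 * (lo + hi);
    // quadratic convergence: a sub-1e-14 relative step means u is converged
    if (std::fabs(un - u) <= 1e-14 * std::max(1.0, u)) { u = un; break; }
    u = un;
  }
  return u / gamma;
}

// exported for direct cross-checking against the R-level sampler
// [[Rcpp::export]]
double cpp_solve_tau(double a, double c, double e, double gamma) {
  return solve_tau(a, c, e, gamma);
}

// ---------- PDMP engine ----------
// presence: n_phases x n_signals (0/1); durations: per-phase lengths;
// snap_times: recorded during the final phase, measured from its start.
// [[Rcpp::export]]
List cpp_pdmp_ensemble(List netL, NumericMatrix presence,
                       NumericVector durations, NumericVector snap_times,
                       int n_paths, double seed, bool record_events,
                       NumericMatrix init_x, IntegerMatrix init_occ) {
  Net net = parse_net(netL);
  const int nG = net.nG, nSp = net.nG + net.nS, nSlots = net.nSlots;
  const int nPhase = durations.size(), nSnap = snap_times.size();
  const bool has_init = init_x.nrow() > 0;

  NumericMatrix final_x(n_paths, nG);
  IntegerMatrix final_occ(n_paths, nSlots);
  NumericVector n_events(n_paths);
  std::vector<NumericMatrix> snaps;
  for (int i = 0; i < nSnap; ++i) snaps.push_back(NumericMatrix(n_paths, nG));
  std::vector<double> ev_time; std::vector<int> ev_kind, ev_slot;

  std::vector<double> x(nSp), alpha(nG), lamb(nSlots), lamu(nSlots);
  std::vector<int> occ(nSlots), btot(nG), bact(nG), brep(nG);

  for (int p = 0; p < n_paths; ++p) {
    Xoshiro rng((uint64_t)(int64_t)seed, (uint64_t)p);
    std::fill(occ.begin(), occ.end(), 0);
    std::fill(btot.begin(), btot.end(), 0);
    std::fill(bact.begin(), bact.end(), 0);
    std::fill(brep.begin(), brep.end(), 0);
    std::fill(x.begin(), x.end(), 0.0);
    if (has_init) {
      for (int g = 0; g < nG; ++g) x[g] = init_x(p, g);
      for (int s = 0; s < nSlots; ++s) {
        occ[s] = init_occ(p, s);
        int g = net.slot_gene[s];
        btot[g] += occ[s];
        if (net.slot_sign[s] > 0) bact[g] += occ[s]; else brep[g] += occ[s];
      }
    }
    for (int g = 0; g < nG; ++g) alpha[g] = gene_alpha(net, g, bact[g], brep[g]);
    double t_global = 0.0, nev = 0.0;

    for (int f = 0; f < nPhase; ++f) {
      for (int s = 0; s < net.nS; ++s) x[nG + s] = presence(f, s);
      const bool last = (f == nPhase - 1);
      const double T = durations[f];
      int si = 0;
      double t = 0.0;
      if (T <= 0 && !(last && nSnap > 0)) continue;
      for (;;) {
        // total hazard Lambda(tau) = a + c*exp(-gamma*tau)
        double a = 0.0, c = 0.0;
        for (int s = 0; s < nSlots; ++s) {
          int g = net.slot_gene[s], r = net.slot_reg[s];
          int free_s = net.N - btot[g];
          if (free_s > 0) {
            double A, B;
            if (r < nG) { A = alpha[r] / net.gamma; B = x[r] - A; }
            else { A = x[r]; B = 0.0; }
            a += free_s * net.kon * A;
            c += free_s * net.kon * B;
          }
          a += occ[s] * net.koff;
        }
        double tau = (a <= 0 && c <= 0) ? R_PosInf
                                        : solve_tau(a, c, rng.expo(), net.gamma);
        double t_next = t + tau;
        if (last) {
          while (si < nSnap && snap_times[si] <= std::min(t_next, T)) {
            double Em = std::exp(-net.gamma * (snap_times[si] - t));
            for (int g = 0; g < nG; ++g)
              snaps[si](p, g) = alpha[g] + (x[g] - alpha[g]) * Em;
            ++si;
          }
        }
        if (!(t_next < T)) {  // no further event in this phase
          double Em = std::exp(-net.gamma * (T - t));
          for (int g = 0; g < nG; ++g)
            x[g] = alpha[g] + (x[g] - alpha[g]) * Em;
          break;
        }
        // advance densities to the event (continuous across it)
        double Em = std::exp(-net.gamma * tau);
        for (int g = 0; g < nG; ++g)
          x[g] = alpha[g] + (x[g] - alpha[g]) * Em;
        t = t_next;
        // competing-risks selection at the event time
        double tot = 0.0;
        for (int s = 0; s < nSlots; ++s) {
          int g = net.slot_gene[s], r = net.slot_reg[s];
          int free_s = net.N - btot[g];
          lamb[s] = free_s > 0 ? free_s * net.kon * x[r] : 0.0;
          lamu[s] = occ[s] * net.koff;
          tot += lamb[s] + lamu[s];
        }
        double thr = rng.unif() * tot, cum = 0.0;
        int slot = -1, kind = 0;  // 0 = bind, 1 = unbind
        for (int s = 0; s < nSlots && slot < 0; ++s) {
          cum += lamb[s];
          if (thr < cum) { slot = s; kind = 0; }
        }
        for (int s = 0; s < nSlots && slot < 0; ++s) {
          cum += lamu[s];
          if (thr < cum) { slot = s; kind = 1; }
        }
        if (slot < 0) {  // round-off guard: take the last active channel
          for (int s = nSlots - 1; s >= 0; --s)
            if (lamu[s] > 0 || lamb[s] > 0) {
              slot = s; kind = lamu[s] > 0 ? 1 : 0; break;
            }
          if (slot < 0) continue;
        }
        int g = net.slot_gene[slot];
        int d = kind == 0 ? 1 : -1;
        occ[slot] += d; btot[g] += d;
        if (net.slot_sign[slot] > 0) bact[g] += d; else brep[g] += d;
        alpha[g] = gene_alpha(net, g, bact[g], brep[g]);
        nev += 1.0;
        if (record_events) {
          ev_time.push_back(t_global + t);
          ev_kind.push_back(kind);
          ev_slot.push_back(slot);
        }
      }
      t_global += T;
    }
    for (int g = 0; g < nG; ++g) final_x(p, g) = x[g];
    for (int s = 0; s < nSlots; ++s) final_occ(p, s) = occ[s];
    n_events[p] = nev;
  }

  List snapL(nSnap);
  for (int i = 0; i < nSnap; ++i) snapL[i] = snaps[i];
  List out = List::create(_["final"] = final_x, _["final_occ"] = final_occ,
                          _["n_events"] = n_events, _["snapshots"] = snapL);
  if (record_events)
    out["events"] = List::create(_["time"] = wrap(ev_time),
                                 _["kind"] = wrap(ev_kind),
                                 _["slot"] = wrap(ev_slot));
  return out;
}

// ---------- SSA engine ----------
// Reaction set per Eqs of the model: bind (free sites * k_on/Omega * P_j),
// unbind (bound * k_off), produce (Omega * alpha_i), degrade (gamma * P_i,
// free copies only; bound copies are protected). Signal species are held at
// a fixed count Omega when present and are never decremented on binding.
// [[Rcpp::export]]
List cpp_ssa_ensemble(List netL, NumericVector presence, double omega,
                      double t_end, NumericVector snap_times, int n_paths,
                      double seed) {
  Net net = parse_net(netL);
  const int nG = net.nG, nSp = net.nG + net.nS, nSlots = net.nSlots;
  const int nSnap = snap_times.size();
  const int nProp = 2 * nSlots + 2 * nG;

  NumericMatrix final_x(n_paths, nG);      // counts / Omega
  IntegerMatrix final_occ(n_paths, nSlots);
  NumericVector n_events(n_paths);
  std::vector<NumericMatrix> snaps;
  for (int i = 0; i < nSnap; ++i) snaps.push_back(NumericMatrix(n_paths, nG));

  std::vector<double> P(nSp), prop(nProp), alpha(nG);
  std::vector<int> occ(nSlots), btot(nG), bact(nG), brep(nG);
  double total = 0.0;

  // propensity layout: [0,nSlots) bind, [nSlots,2*nSlots) unbind,
  // then produce per gene, then degrade per gene
  auto set_prop = [&](int idx, double v) {
    total += v - prop[idx];
    prop[idx] = v;
  };
  auto upd_bind = [&](int s) {
    int g = net.slot_gene[s];
    int free_s = net.N - btot[g];
    set_prop(s, free_s > 0 ? free_s * net.kon / omega * P[net.slot_reg[s]] : 0.0);
  };
  auto upd_unbind = [&](int s) { set_prop(nSlots + s, occ[s] * net.koff); };
  auto upd_produce = [&](int g) { set_prop(2 * nSlots + g, omega * alpha[g]); };
  auto upd_degrade = [&](int g) { set_prop(2 * nSlots + nG + g, net.gamma * P[g]); };
  auto changeP = [&](int r) {  // copy number of gene-product r changed
    upd_degrade(r);
    for (size_t k = 0; k < net.slots_of_reg_gene[r].size(); ++k)
      upd_bind(net.slots_of_reg_gene[r][k]);
  };
  auto changeOcc = [&](int s) {  // occupancy of slot s changed
    int g = net.slot_gene[s];
    for (size_t k = 0; k < net.slots_of_gene[g].size(); ++k)
      upd_bind(net.slots_of_gene[g][k]);
    upd_unbind(s);
    alpha[g] = gene_alpha(net, g, bact[g], brep[g]);
    upd_produce(g);
  };

  for (int p = 0; p < n_paths; ++p) {
    Xoshiro rng((uint64_t)(int64_t)seed, (uint64_t)p);
    std::fill(P.begin(), P.end(), 0.0);
    for (int s = 0; s < net.nS; ++s) P[nG + s] = presence[s] * omega;
    std::fill(occ.begin(), occ.end(), 0);
    std::fill(btot.begin(), btot.end(), 0);
    std::fill(bact.begin(), bact.end(), 0);
    std::fill(brep.begin(), brep.end(), 0);
    for (int g = 0; g < nG; ++g) alpha[g] = gene_alpha(net, g, 0, 0);
    total = 0.0;
    std::fill(prop.begin(), prop.end(), 0.0);
    for (int s = 0; s < nSlots; ++s) { upd_bind(s); upd_unbind(s); }
    for (int g = 0; g < nG; ++g) { upd_produce(g); upd_degrade(g); }

    double t = 0.0, nev = 0.0;
    int si = 0;
    long refresh = 0;
    for (;;) {
      if (total <= 0) {  // absorbing: flush snapshots and stop
        while (si < nSnap) {
          for (int g = 0; g < nG; ++g) snaps[si](p, g) = P[g] / omega;
          ++si;
        }
        break;
      }
      double t_next = t + rng.expo() / total;
      while (si < nSnap && snap_times[si] <= std::min(t_next, t_end)) {
        for (int g = 0; g < nG; ++g) snaps[si](p, g) = P[g] / omega;
        ++si;
      }
      if (!(t_next < t_end)) break;
      t = t_next;
      double thr = rng.unif() * total, cum = 0.0;
      int idx = -1;
      for (int i = 0; i < nProp; ++i) {
        cum += prop[i];
        if (thr < cum) { idx = i; break; }
      }
      if (idx < 0) idx = nProp - 1;
      if (idx < nSlots) {                       // bind
        int s = idx, g = net.slot_gene[s], r = net.slot_reg[s];
        occ[s] += 1; btot[g] += 1;
        if (net.slot_sign[s] > 0) bact[g] += 1; else brep[g] += 1;
        if (r < nG) { P[r] -= 1.0; changeP(r); }  // signals not decremented
        changeOcc(s);
      } else if (idx < 2 * nSlots) {            // unbind
        int s = idx - nSlots, g = net.slot_gene[s], r = net.slot_reg[s];
        occ[s] -= 1; btot[g] -= 1;
        if (net.slot_sign[s] > 0) bact[g] -= 1; else brep[g] -= 1;
        if (r < nG) { P[r] += 1.0; changeP(r); }
        changeOcc(s);
      } else if (idx < 2 * nSlots + nG) {       // produce
        int g = idx - 2 * nSlots;
        P[g] += 1.0; changeP(g);
      } else {                                  // degrade
        int g = idx - 2 * nSlots - nG;
        P[g] -= 1.0; changeP(g);
      }
      nev += 1.0;
      if (((++refresh) & 0xFFFFF) == 0) {  // periodic drift control
        total = 0.0;
        for (int i = 0; i < nProp; ++i) total += prop[i];
      }
    }
    for (int g = 0; g < nG; ++g) final_x(p, g) = P[g] / omega;
    for (int s = 0; s < nSlots; ++s) final_occ(p, s) = occ[s];
    n_events[p] = nev;
  }

  List snapL(nSnap);
  for (int i = 0; i < nSnap; ++i) snapL[i] = snaps[i];
  return List::create(_["final"] = final_x, _["final_occ"] = final_occ,
                      _["n_events"] = n_events, _["snapshots"] = snapL);
}
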