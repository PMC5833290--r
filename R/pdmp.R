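#' Deterministic density flow between promoter events
#'
#' Between promoter events each TF density relaxes exponentially toward its
#' production/degradation balance: dx/dt = alpha - gamma x, whose exact
#' solution is `alpha/gamma + (x0 - alpha/gamma) * exp(-gamma dt)`.
#'
#' @param x0 density at the start of the interval.
#' @param alpha production rate over the interval.
#' @param dt non-negative duration.
#' @param gamma degradation rate (1 in non-dimensional units).
#' @return Density after `dt`; vectorized over its arguments.
#' @export
flow <- function(x0, alpha, dt, gamma = 1) {
  if (any(dt < 0)) stop("dt must be non-negative")
  alpha / gamma + (x0 - alpha / gamma) * exp(-gamma * dt)
}

#' Construct a system state
#'
#' A `pdmp_state` bundles the per-gene promoter occupancy (how many sites
#' are bound by which regulator), the real-valued TF densities, the clock,
#' and the signal condition. Signal species have fixed density 1 (present)
#' or 0 (absent) and are not part of `densities`.
#'
#' @param top a `pdmp_topology`.
#' @param condition a `pdmp_condition`.
#' @param densities named numeric over genes (default all 0).
#' @param promoter named list over genes of named integer vectors (sites
#'   bound per regulator); default all unbound.
#' @param time non-negative clock value.
#' @return An object of class `pdmp_state`.
#' @export
system_state <- function(top, condition, densities = NULL, promoter = NULL,
                         time = 0) {
  gs <- genes(top)
  if (is.null(densities)) densities <- stats::setNames(numeric(length(gs)), gs)
  stopifnot(setequal(names(densities), gs), all(densities >= 0))
  if (is.null(promoter))
    promoter <- stats::setNames(lapply(gs, function(g) integer(0)), gs)
  structure(list(time = time, densities = densities[gs],
                 promoter = promoter[gs], condition = condition),
            class = "pdmp_state")
}

# density of a regulator species as seen from a state: genes use their
# current density, signals are 0/1 from the condition
regulator_density <- function(reg, state) {
  if (reg %in% names(state$densities)) return(unname(state$densities[reg]))
  signal_density(reg, state$condition)
}

#' Summarize the promoter-event hazards of a state
#'
#' Enumerates, for every gene i and regulator j in S_i, a binding channel
#' with instantaneous hazard (free sites of i) * k_on * x_j(t) and an
#' unbinding channel with hazard (sites of i bound by j) * k_off. Because
#' every density follows [flow()], each channel hazard has the form
#' `const + trans * exp(-t)` (time measured from the state's clock), so the
#' total hazard is `Lambda(t) = a_coef + c_coef * exp(-t)` and the
#' integrated hazard `H(t) = a_coef * t + c_coef * (1 - exp(-t))` is
#' available in closed form. Channels with identically zero hazard are
#' omitted.
#'
#' @param state a `pdmp_state`.
#' @param params a `pdmp_params`.
#' @param top a `pdmp_topology`.
#' @return An object of class `pdmp_hazard`: list with `a_coef`, `c_coef`
#'   and a `channels` data.frame (kind, gene, regulator, const_part,
#'   trans_part).
#' @export
hazard_summary <- function(state, params, top) {
  regs <- regulator_sets(top)
  gs <- genes(top)
  alpha <- vapply(gs, function(g)
    production_activity(g, state$promoter[[g]], regs, params)$rate,
    numeric(1))
  kind <- character(0); gene <- character(0); regulator <- character(0)
  const_part <- numeric(0); trans_part <- numeric(0)
  for (g in gs) {
    rset <- c(regs[[g]]$activators, regs[[g]]$repressors)
    if (!length(rset)) next
    occ <- state$promoter[[g]]
    free <- params$n_sites - sum(occ)
    for (r in rset) {
      # binding: free * k_on * x_r(t), x_r(t) = A + B exp(-t)
      if (free > 0 && params$k_on > 0) {
        if (r %in% gs) {
          A <- alpha[[r]] / params$gamma
          B <- unname(state$densities[r]) - A
        } else {
          A <- regulator_density(r, state); B <- 0
        }
        cp <- free * params$k_on * A
        tp <- free * params$k_on * B
        if (cp != 0 || tp != 0) {
          kind <- c(kind, "bind"); gene <- c(gene, g)
          regulator <- c(regulator, r)
          const_part <- c(const_part, cp); trans_part <- c(trans_part, tp)
        }
      }
      nb <- if (r %in% names(occ)) occ[[r]] else 0L
      if (nb > 0 && params$k_off > 0) {
        kind <- c(kind, "unbind"); gene <- c(gene, g)
        regulator <- c(regulator, r)
        const_part <- c(const_part, nb * params$k_off)
        trans_part <- c(trans_part, 0)
      }
    }
  }
  structure(list(a_coef = sum(const_part), c_coef = sum(trans_part),
                 channels = data.frame(kind = kind, gene = gene,
                                       regulator = regulator,
                                       const_part = const_part,
                                       trans_part = trans_part,
                                       stringsAsFactors = FALSE)),
            class = "pdmp_hazard")
}

#' Integrated hazard of a hazard summary
#'
#' `H(t) = a_coef * t + c_coef * (1 - exp(-t))`, non-decreasing with
#' `H(0) = 0`.
#'
#' @param h a `pdmp_hazard`.
#' @param t non-negative time(s) since the summarized state.
#' @return `H(t)`, vectorized.
#' @export
integrated_hazard <- function(h, t) h$a_coef * t + h$c_coef * (1 - exp(-t))

#' Sample the next promoter-event waiting time
#'
#' Inverts the integrated hazard: returns the unique `t* >= 0` with
#' `H(t*) = e` where `e` is a unit-mean exponential deviate. When
#' `a_coef = 0` the cumulative hazard saturates at `c_coef`; if `e` is not
#' reached the function returns `Inf` ("no event"). The closed-form
#' inversion uses the principal Lambert W branch,
#' `t* = d + W((c/a) exp(-d))` with `d = (e - c)/a`; the `"bisection"`
#' method solves the same root by bracketed monotone root-finding. Both
#' agree to the stated tolerance.
#'
#' @param h a `pdmp_hazard` (or any list with `a_coef`, `c_coef`).
#' @param e positive exponential deviate(s).
#' @param method `"lambert"` (closed form, default) or `"bisection"`.
#' @param tol absolute tolerance on `H(t*) - e` (default 1e-12).
#' @return Waiting time(s); `Inf` means no event ever occurs.
#' @export
sample_event_time <- function(h, e, method = c("lambert", "bisection"),
                              tol = 1e-12) {
  method <- match.arg(method)
  if (any(e <= 0)) stop("e must be positive")
  a <- h$a_coef; c_ <- h$c_coef
  solve1 <- function(e1) {
    if (a == 0) {
      if (c_ <= e1) return(Inf)
      return(-log1p(-e1 / c_))
    }
    if (c_ == 0) return(e1 / a)
    if (method == "lambert") {
      d <- (e1 - c_) / a
      arg <- (c_ / a) * exp(-d)
      if (is.finite(arg) && arg >= -exp(-1) * (1 - 1e-12)) {
        w <- pracma::lambertWp(arg)
        t_star <- d + w
        if (is.finite(t_star) && t_star >= 0 &&
            abs(integrated_hazard(h, t_star) - e1) <= tol * max(1, e1))
          return(t_star)
      }
      # underflow/overflow or boundary: fall through to bisection
    }
    f <- function(t) integrated_hazard(h, t) - e1
    hi <- max(1, e1 / a) * 2
    while (f(hi) < 0) hi <- hi * 2
    stats::uniroot(f, c(0, hi), tol = 1e-15)$root
  }
  vapply(e, solve1, numeric(1))
}

#' Select the event channel fired at a waiting time
#'
#' Competing-risks selection: channel k is chosen with probability
#' proportional to its instantaneous hazard evaluated at the event time.
#' Deterministic given `(h, t_event, u)`.
#'
#' @param h a `pdmp_hazard`.
#' @param t_event event time returned by [sample_event_time()].
#' @param u uniform(0,1) deviate.
#' @return One row of `h$channels` (kind, gene, regulator, ...).
#' @export
select_event <- function(h, t_event, u) {
  lam <- h$channels$const_part + h$channels$trans_part * exp(-t_event)
  lam <- pmax(lam, 0)  # guard tiny negative round-off of transient parts
  tot <- sum(lam)
  if (tot <= 0) stop("all channel hazards are zero at t_event")
  idx <- which(u < cumsum(lam) / tot)[1L]
  if (is.na(idx)) idx <- length(lam)
  h$channels[idx, , drop = FALSE]
}

# ---- compiled-engine plumbing ------------------------------------------

# Flatten a topology + parameters into the integer tables consumed by the
# C++ engines. Species are ordered genes first (topology order), then
# signals. Binding slots are (gene, regulator) pairs grouped by gene.
compile_net <- function(top, params) {
  gs <- genes(top); sg <- signals(top)
  species <- c(gs, sg)
  regs <- regulator_sets(top)
  slot_gene <- integer(0); slot_reg <- integer(0); slot_sign <- integer(0)
  for (i in seq_along(gs)) {
    rs <- regs[[gs[i]]]
    for (r in rs$activators) {
      slot_gene <- c(slot_gene, i - 1L)
      slot_reg <- c(slot_reg, match(r, species) - 1L)
      slot_sign <- c(slot_sign, 1L)
    }
    for (r in rs$repressors) {
      slot_gene <- c(slot_gene, i - 1L)
      slot_reg <- c(slot_reg, match(r, species) - 1L)
      slot_sign <- c(slot_sign, -1L)
    }
  }
  has_act <- vapply(gs, function(g) length(regs[[g]]$activators) > 0L, logical(1))
  has_rep <- vapply(gs, function(g) length(regs[[g]]$repressors) > 0L, logical(1))
  list(n_genes = length(gs), n_signals = length(sg),
       gene_names = gs, signal_names = sg,
       slot_gene = slot_gene, slot_reg = slot_reg, slot_sign = slot_sign,
       has_act = as.integer(has_act), has_rep = as.integer(has_rep),
       n_sites = params$n_sites, k_on = params$k_on, k_off = params$k_off,
       alpha_m = params$alpha_m, alpha_max = params$alpha_max,
       gamma = params$gamma)
}

condition_presence <- function(top, condition) {
  vapply(signals(top), signal_density, numeric(1), condition = condition)
}

#' Simulate one exact PDMP sample path
#'
#' Repeats: summarize hazards, draw the exact waiting time by closed-form
#' inversion of the integrated hazard, advance all densities by the
#' deterministic flow, fire the selected binding/unbinding event, and update
#' the per-gene production rates through the molecular logic. Densities are
#' continuous across events. Fully reproducible given `seed`.
#'
#' @param top a `pdmp_topology`.
#' @param params a `pdmp_params`.
#' @param condition a `pdmp_condition`.
#' @param t_end simulation horizon (> 0), non-dimensional time.
#' @param seed integer seed (mandatory; the engine keeps its own
#'   per-path RNG streams and does not touch R's RNG).
#' @param snapshot_times optional increasing times at which densities are
#'   recorded.
#' @return A `pdmp_path`: list with `events` (data.frame: time, kind, gene,
#'   regulator), `final` (named densities at `t_end`), `snapshots`
#'   (matrix times x genes, if requested), and `promoter` (final occupancy).
#' @export
simulate_path <- function(top, params, condition, t_end, seed,
                          snapshot_times = NULL) {
  stopifnot(t_end > 0)
  ens <- simulate_ensemble(top, params, condition, n_paths = 1L,
                           t_end = t_end, seed = seed,
                           snapshot_times = snapshot_times,
                           record_events = TRUE)
  ev <- attr(ens, "events")
  snaps <- attr(ens, "snapshots")
  snap_m <- NULL
  if (!is.null(snaps)) {
    snap_m <- do.call(rbind, lapply(snaps$states, function(m) m[1L, ]))
    rownames(snap_m) <- snaps$times
  }
  structure(list(events = ev,
                 final = stats::setNames(as.numeric(ens[1L, ]), colnames(ens)),
                 snapshots = snap_m,
                 promoter = attr(ens, "final_promoter"),
                 condition = condition, params = params, t_end = t_end),
            class = "pdmp_path")
}

#' Simulate an ensemble of independent PDMP paths
#'
#' Paths are independent with deterministically derived per-path RNG
#' streams (splitmix-spawned from `seed` and the path index), so the
#' ensemble is reproducible and independent of execution order.
#'
#' @inheritParams simulate_path
#' @param n_paths number of independent paths (>= 1).
#' @param init optional `pdmp_ensemble` whose final states (densities and
#'   promoter occupancy) seed the paths, e.g. for signal-switch experiments;
#'   must have been simulated on the same topology with the same `n_paths`.
#' @param record_events record the event log (only with `n_paths = 1`).
#' @return A `pdmp_ensemble`: numeric matrix `n_paths x genes` of final
#'   densities with attributes `condition`, `time`, `params`, `seed`,
#'   `n_events` (events per path) and, if requested, `snapshots` (list with
#'   `times` and `states`, one matrix per time).
#' @export
simulate_ensemble <- function(top, params, condition, n_paths, t_end, seed,
                              snapshot_times = NULL, init = NULL,
                              record_events = FALSE) {
  stopifnot(n_paths >= 1, t_end >= 0)
  net <- compile_net(top, params)
  pres <- matrix(condition_presence(top, condition), nrow = 1)
  durations <- c(0, t_end)  # no distinct burn phase: single condition
  pres2 <- rbind(pres, pres)
  run_engine(net, pres2, durations, snapshot_times, n_paths, seed,
             record_events, init, condition, params, top)
}

run_engine <- function(net, presence, durations, snapshot_times, n_paths,
                       seed, record_events, init, condition, params, top) {
  if (is.null(snapshot_times)) snapshot_times <- numeric(0)
  stopifnot(!is.unsorted(snapshot_times))
  init_x <- matrix(-1, 0, 0); init_occ <- matrix(0L, 0, 0)
  if (!is.null(init)) {
    stopifnot(inherits(init, "pdmp_ensemble"),
              nrow(init) == n_paths,
              identical(colnames(init), net$gene_names))
    init_x <- unclass(init)
    attributes(init_x) <- attributes(init_x)["dim"]
    colnames(init_x) <- NULL
    init_occ <- attr(init, "final_promoter_raw")
    if (is.null(init_occ))
      stop("init ensemble lacks promoter occupancy; simulate it with pdmpnet >= 0.1")
  }
  res <- cpp_pdmp_ensemble(net, presence, as.numeric(durations),
                           as.numeric(snapshot_times),
                           as.integer(n_paths), as.numeric(seed),
                           isTRUE(record_events), init_x, init_occ)
  m <- res$final
  colnames(m) <- net$gene_names
  out <- structure(m, class = c("pdmp_ensemble", class(m)),
                   condition = condition$label,
                   time = sum(durations),
                   params = params, seed = seed,
                   n_events = as.numeric(res$n_events),
                   final_promoter_raw = res$final_occ)
  if (length(snapshot_times)) {
    states <- lapply(res$snapshots, function(s) {
      colnames(s) <- net$gene_names; s
    })
    attr(out, "snapshots") <- list(times = snapshot_times, states = states)
  }
  if (isTRUE(record_events)) {
    ev <- res$events
    df <- data.frame(time = ev$time,
                     kind = c("bind", "unbind")[ev$kind + 1L],
                     gene = net$gene_names[net$slot_gene[ev$slot + 1L] + 1L],
                     regulator = c(net$gene_names, net$signal_names)[
                       net$slot_reg[ev$slot + 1L] + 1L],
                     stringsAsFactors = FALSE)
    attr(out, "events") <- df
    attr(out, "final_promoter") <- promoter_from_raw(res$final_occ[1L, ], net)
  }
  out
}

promoter_from_raw <- function(occ_row, net) {
  species <- c(net$gene_names, net$signal_names)
  out <- stats::setNames(vector("list", net$n_genes), net$gene_names)
  for (i in seq_len(net$n_genes)) {
    idx <- which(net$slot_gene == i - 1L)
    v <- as.integer(occ_row[idx])
    names(v) <- species[net$slot_reg[idx] + 1L]
    out[[i]] <- v[v != 0L]
  }
  out
}

#' @export
print.pdmp_ensemble <- function(x, ...) {
  cat(sprintf("<pdmp_ensemble> %d paths x %d genes, condition %s, t = %g\n",
              nrow(x), ncol(x), attr(x, "condition"), attr(x, "time")))
  invisible(x)
}
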