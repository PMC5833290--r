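#' Enumerate the individual-based reaction set
#'
#' The full mass-action system underlying the PDMP: for every gene i and
#' regulator j in S_i a binding reaction (propensity
#' `free sites * k_on / Omega * P_j`) and an unbinding reaction
#' (`bound(i,j) * k_off`); for every gene a production reaction
#' (`Omega * alpha_i`, with alpha_i set by the promoter configuration) and a
#' degradation reaction (`gamma * P_i`, free copies only — promoter-bound
#' copies are protected). Signal species are held at a fixed count
#' `Omega` (present) or 0 (absent).
#'
#' @param top a `pdmp_topology`.
#' @param params a `pdmp_params`.
#' @param condition a `pdmp_condition`.
#' @return data.frame with one row per reaction: `kind`
#'   (bind/unbind/produce/degrade), `gene`, `regulator` (NA for
#'   produce/degrade) and `propensity_at` — a list-column of functions of a
#'   `pdmp_ssa_state`-like list `(counts, promoter)` returning the
#'   propensity.
#' @export
build_reaction_set <- function(top, params, condition) {
  regs <- regulator_sets(top)
  gs <- genes(top)
  omega <- params$omega
  sig_count <- function(s)
    omega * switch(s, LIF = condition$lif, CH = condition$ch,
                   PD = condition$pd)
  rows <- list()
  for (g in gs) {
    rset <- c(regs[[g]]$activators, regs[[g]]$repressors)
    for (r in rset) {
      rows[[length(rows) + 1L]] <- list(
        kind = "bind", gene = g, regulator = r,
        propensity_at = local({
          g0 <- g; r0 <- r
          function(state) {
            free <- params$n_sites - sum(state$promoter[[g0]])
            cnt <- if (r0 %in% gs) state$counts[[r0]] else sig_count(r0)
            free * params$k_on / omega * cnt
          }
        }))
      rows[[length(rows) + 1L]] <- list(
        kind = "unbind", gene = g, regulator = r,
        propensity_at = local({
          g0 <- g; r0 <- r
          function(state) {
            occ <- state$promoter[[g0]]
            nb <- if (r0 %in% names(occ)) occ[[r0]] else 0L
            nb * params$k_off
          }
        }))
    }
    rows[[length(rows) + 1L]] <- list(
      kind = "produce", gene = g, regulator = NA_character_,
      propensity_at = local({
        g0 <- g
        function(state)
          omega * production_activity(g0, state$promoter[[g0]], regs,
                                      params)$rate
      }))
    rows[[length(rows) + 1L]] <- list(
      kind = "degrade", gene = g, regulator = NA_character_,
      propensity_at = local({
        g0 <- g
        function(state) params$gamma * state$counts[[g0]]
      }))
  }
  out <- data.frame(kind = vapply(rows, `[[`, "", "kind"),
                    gene = vapply(rows, `[[`, "", "gene"),
                    regulator = vapply(rows, `[[`, "", "regulator"),
                    stringsAsFactors = FALSE)
  out$propensity_at <- lapply(rows, `[[`, "propensity_at")
  out
}

#' Simulate the individual-based model (Gillespie SSA)
#'
#' Statistically exact kinetic Monte Carlo simulation of the reaction set of
#' [build_reaction_set()] at integer copy-number resolution, used to
#' validate the PDMP approximation (whose error is O(1/Omega)). Paths start
#' from empty promoters and zero copy numbers.
#'
#' @inheritParams simulate_ensemble
#' @param omega population scale (overrides `params$omega` if given).
#' @return A `pdmp_ensemble` of final TF densities (counts / Omega), with
#'   the same attributes as the PDMP version plus `engine = "ssa"`. If
#'   `snapshot_times` is supplied, densities are also recorded at those
#'   times.
#' @export
simulate_ssa <- function(top, params, condition, n_paths, t_end, seed,
                         snapshot_times = NULL, omega = NULL) {
  stopifnot(n_paths >= 1, t_end > 0)
  if (is.null(omega)) omega <- params$omega
  stopifnot(omega >= 1)
  net <- compile_net(top, params)
  if (is.null(snapshot_times)) snapshot_times <- numeric(0)
  stopifnot(!is.unsorted(snapshot_times))
  res <- cpp_ssa_ensemble(net, condition_presence(top, condition),
                          as.numeric(omega), as.numeric(t_end),
                          as.numeric(snapshot_times),
                          as.integer(n_paths), as.numeric(seed))
  m <- res$final
  colnames(m) <- net$gene_names
  out <- structure(m, class = c("pdmp_ensemble", class(m)),
                   condition = condition$label, time = t_end,
                   params = params, seed = seed, engine = "ssa",
                   omega = omega,
                   n_events = as.numeric(res$n_events),
                   final_promoter_raw = res$final_occ)
  if (length(snapshot_times)) {
    states <- lapply(res$snapshots, function(s) {
      colnames(s) <- net$gene_names; s
    })
    attr(out, "snapshots") <- list(times = snapshot_times, states = states)
  }
  out
}
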