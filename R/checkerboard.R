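#' Stationary mean-expression matrix
#'
#' Simulates an independent PDMP ensemble per condition to stationarity and
#' records the ensemble mean density of every TF: entry (i, c) is the mean
#' of x_i under condition c. Because of non-dimensionalization all entries
#' lie in [0, 1].
#'
#' @param top a `pdmp_topology`.
#' @param params a `pdmp_params`.
#' @param conditions list of `pdmp_condition` (or character labels).
#' @param n_paths paths per condition (default 1000).
#' @param t_end burn-in horizon per path (default 50 time units, about 50
#'   TF lifetimes).
#' @param seed integer seed; per-condition seeds are derived
#'   deterministically.
#' @return Numeric matrix genes x conditions with condition labels as
#'   column names.
#' @export
mean_expression_matrix <- function(top, params, conditions,
                                   n_paths = 1000L, t_end = 50, seed = 1L) {
  conditions <- lapply(conditions, function(co)
    if (is.character(co)) parse_condition(co) else co)
  labs <- vapply(conditions, `[[`, "", "label")
  cols <- lapply(seq_along(conditions), function(i) {
    ens <- simulate_ensemble(top, params, conditions[[i]], n_paths = n_paths,
                             t_end = t_end, seed = seed * 1000L + i)
    colMeans(ens)
  })
  m <- do.call(cbind, cols)
  colnames(m) <- labs
  m
}

#' Binarize an expression matrix
#'
#' A TF is classified as expressed (1) in a condition iff its mean density
#' is strictly greater than the uniform threshold `eta`; exact ties count
#' as not expressed.
#'
#' @param m numeric matrix in `[0, 1]`.
#' @param eta threshold, strictly inside (0, 1).
#' @return Integer 0/1 matrix of the same shape and dimnames.
#' @export
binarize <- function(m, eta) {
  if (!is.numeric(eta) || length(eta) != 1L || eta <= 0 || eta >= 1)
    stop("eta must be a single value strictly inside (0, 1)")
  out <- (m > eta) + 0L
  dimnames(out) <- dimnames(m)
  out
}

#' Hamming distance between binary matrices
#'
#' The number of cell-wise discrepancies between two equal-shaped binary
#' matrices with identical row/column labels (when labelled).
#'
#' @param a,b binary matrices.
#' @return Non-negative integer count.
#' @export
hamming_distance <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("matrices have different shapes")
  if (!is.null(dimnames(a)) && !is.null(dimnames(b)) &&
      !identical(dimnames(a), dimnames(b)))
    stop("matrices have different row/column labels")
  sum(a != b)
}

#' Threshold-optimized fit against a benchmark pattern
#'
#' Scans a grid of thresholds eta, binarizes the mean-expression matrix at
#' each, and returns the fit at the eta minimizing the Hamming distance to
#' the benchmark (ties broken toward the smallest eta). The default grid is
#' exhaustive: all midpoints between consecutive sorted matrix values
#' (plus flanking values), since the Hamming distance is piecewise constant
#' in eta.
#'
#' @param m numeric mean-expression matrix.
#' @param benchmark binary matrix of the same shape/labels.
#' @param eta_grid optional numeric vector of candidate thresholds in (0,1).
#' @param params optional `pdmp_params` recorded in the result.
#' @return A `pdmp_fit`: list with `eta`, `hamming`, `mismatch` (logical
#'   mask), `binarized`, `params`.
#' @export
optimal_threshold <- function(m, benchmark, eta_grid = NULL, params = NULL) {
  if (is.null(eta_grid)) {
    v <- sort(unique(as.numeric(m)))
    mids <- if (length(v) > 1L) (v[-1L] + v[-length(v)]) / 2 else numeric(0)
    # midpoints cover every binarization between observed values; the flank
    # candidates cover the all-ones (below min) and all-zeros (above max)
    # binarizations
    eta_grid <- c(mids, v + 1e-9, max(v[1L] / 2, 1e-9))
    eta_grid <- sort(unique(pmin(pmax(eta_grid, 1e-9), 1 - 1e-9)))
  }
  if (!length(eta_grid) || any(eta_grid <= 0) || any(eta_grid >= 1))
    stop("eta_grid must be non-empty within (0, 1)")
  hd <- vapply(eta_grid, function(eta)
    hamming_distance(binarize(m, eta), benchmark), numeric(1))
  i <- which.min(hd)  # first minimum = smallest eta on a sorted grid
  bin <- binarize(m, eta_grid[i])
  structure(list(eta = eta_grid[i], hamming = as.integer(hd[i]),
                 mismatch = bin != benchmark, binarized = bin,
                 params = params),
            class = "pdmp_fit")
}

#' @export
print.pdmp_fit <- function(x, ...) {
  cat(sprintf("<pdmp_fit> Hamming distance %d at eta = %.4g\n",
              x$hamming, x$eta))
  invisible(x)
}

#' Parameter sweep against the benchmark pattern
#'
#' Simulates the stationary mean-expression matrix at every row of a
#' parameter grid, threshold-optimizes each against the benchmark, and
#' returns one record per grid point. Completed rows can be checkpointed to
#' a TSV so an interrupted sweep resumes where it stopped; the grid-point
#' order is deterministic, so resumed and uninterrupted sweeps are
#' identical.
#'
#' @param top a `pdmp_topology`.
#' @param benchmark binary matrix whose column labels name the conditions
#'   to simulate.
#' @param grid data.frame with columns `alpha_m`, `k_on`, `k_off`,
#'   `n_sites`.
#' @param n_paths paths per condition per grid point (default 300).
#' @param t_end burn-in horizon (default 30).
#' @param seed integer seed.
#' @param checkpoint optional TSV path for incremental/restartable results.
#' @return data.frame: grid columns plus `eta` and `hamming`.
#' @export
sweep_hamming <- function(top, benchmark, grid, n_paths = 300L, t_end = 30,
                          seed = 1L, checkpoint = NULL) {
  stopifnot(all(c("alpha_m", "k_on", "k_off", "n_sites") %in% names(grid)))
  conditions <- lapply(colnames(benchmark), parse_condition)
  done <- NULL
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    done <- utils::read.delim(checkpoint)
    if (nrow(done) > nrow(grid)) done <- NULL
  }
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    if (!is.null(done) && i <= nrow(done)) {
      rows[[i]] <- done[i, , drop = FALSE]
      next
    }
    p <- model_params(n_sites = grid$n_sites[i], k_on = grid$k_on[i],
                      k_off = grid$k_off[i], alpha_m = grid$alpha_m[i])
    m <- mean_expression_matrix(top, p, conditions, n_paths = n_paths,
                                t_end = t_end, seed = seed + i)
    fit <- optimal_threshold(m, benchmark, params = p)
    rows[[i]] <- data.frame(alpha_m = grid$alpha_m[i], k_on = grid$k_on[i],
                            k_off = grid$k_off[i], n_sites = grid$n_sites[i],
                            eta = fit$eta, hamming = fit$hamming)
    if (!is.null(checkpoint))
      utils::write.table(do.call(rbind, rows[seq_len(i)]), checkpoint,
                         sep = "\t", row.names = FALSE, quote = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Default coarse sweep grid
#'
#' A ~200-point grid anchored at the three named parameter regimes: the
#' full cross of `alpha_m` in {0.005, 0.01, 0.02, 0.05}, `k_on` in
#' {1, 3.2, 10, 16, 32, 64, 102} and `k_off` in
#' {0.1, 0.2, 0.5, 1, 1.5, 3.2, 10}, at a fixed number of promoter sites.
#' The grid contains the slow (3.2, 0.2, 0.02), intermediate (16, 1.5,
#' 0.01) and fast (102, 10, 0.005) points.
#'
#' @param n_sites promoter sites per gene for every grid point.
#' @return data.frame with columns `alpha_m`, `k_on`, `k_off`, `n_sites`.
#' @export
default_sweep_grid <- function(n_sites = 1L) {
  g <- expand.grid(alpha_m = c(0.005, 0.01, 0.02, 0.05),
                   k_on = c(1, 3.2, 10, 16, 32, 64, 102),
                   k_off = c(0.1, 0.2, 0.5, 1, 1.5, 3.2, 10),
                   KEEP.OUT.ATTRS = FALSE)
  g$n_sites <- as.integer(n_sites)
  g
}

#' Reference parameter regimes of the mESC fit
#'
#' The three named points in the low-Hamming "valley" of the N = 2
#' parameter landscape: slow (k_on 3.2, k_off 0.2, alpha_m 0.02),
#' intermediate (16, 1.5, 0.01) and fast (102, 10, 0.005) promoter
#' switching relative to the TF lifetime.
#'
#' @param regime one of `"slow"`, `"intermediate"`, `"fast"`.
#' @param n_sites promoter sites per gene (default 2).
#' @return A `pdmp_params`.
#' @export
regime_params <- function(regime = c("intermediate", "slow", "fast"),
                          n_sites = 2L) {
  regime <- match.arg(regime)
  switch(regime,
         slow = model_params(n_sites, 3.2, 0.2, 0.02),
         intermediate = model_params(n_sites, 16, 1.5, 0.01),
         fast = model_params(n_sites, 102, 10, 0.005))
}
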