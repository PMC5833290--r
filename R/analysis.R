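#' Analysis configuration
#'
#' Defaults for the ensemble analyses: the Jensen-Shannon divergence
#' threshold defining a completed transition (0.3), the number of
#' histogram bins (50 uniform bins over `[0, 1.02]`, slightly past the
#' non-dimensional density ceiling so boundary mass is kept), the snapshot
#' cadence (0.25 time units), and the PCA reference condition.
#'
#' @param jsd_threshold transition threshold in (0, 1).
#' @param bins histogram bin count.
#' @param xlim shared histogram support.
#' @param cadence snapshot spacing in non-dimensional time.
#' @param reference PCA baseline condition label.
#' @param use_distance if `TRUE`, threshold the Jensen-Shannon *distance*
#'   (the square root of the divergence) instead of the divergence.
#' @return A list of class `pdmp_analysis_config`.
#' @export
analysis_config <- function(jsd_threshold = 0.3, bins = 50L,
                            xlim = c(0, 1.02), cadence = 0.25,
                            reference = "LIF+2i", use_distance = FALSE) {
  stopifnot(jsd_threshold > 0, jsd_threshold < 1, bins >= 2)
  structure(list(jsd_threshold = jsd_threshold, bins = as.integer(bins),
                 xlim = xlim, cadence = cadence, reference = reference,
                 use_distance = use_distance),
            class = "pdmp_analysis_config")
}

#' Normalized marginal histogram of one TF
#'
#' @param ensemble a `pdmp_ensemble` (or plain matrix with gene columns).
#' @param gene_id gene column to summarize.
#' @param bins number of uniform bins.
#' @param xlim support shared across compared histograms.
#' @return A `pdmp_marginal`: list with `gene`, `edges` (length bins + 1)
#'   and `mass` (sums to 1).
#' @export
marginal_histogram <- function(ensemble, gene_id, bins = 50L,
                               xlim = c(0, 1.02)) {
  if (!nrow(ensemble)) stop("empty ensemble")
  x <- ensemble[, gene_id]
  edges <- seq(xlim[1], xlim[2], length.out = bins + 1L)
  x <- pmin(pmax(x, xlim[1]), xlim[2])  # clamp stray boundary values
  counts <- tabulate(findInterval(x, edges, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = bins)
  structure(list(gene = gene_id, edges = edges, mass = counts / sum(counts)),
            class = "pdmp_marginal")
}

#' Jensen-Shannon divergence between two histograms
#'
#' `JSD(p, q) = KL(p || m)/2 + KL(q || m)/2` with `m = (p + q)/2`,
#' logarithms base 2, so the value lies in `[0, 1]` (1 for disjoint
#' supports). The convention `0 * log(0/.) = 0` applies.
#'
#' @param p,q `pdmp_marginal` objects on identical bin edges, or bare
#'   probability vectors of equal length.
#' @param distance return the Jensen-Shannon distance (square root of the
#'   divergence) instead.
#' @return Scalar in `[0, 1]`.
#' @export
js_divergence <- function(p, q, distance = FALSE) {
  if (inherits(p, "pdmp_marginal") || inherits(q, "pdmp_marginal")) {
    if (!isTRUE(all.equal(p$edges, q$edges)))
      stop("histograms have mismatched bin edges")
    p <- p$mass; q <- q$mass
  }
  if (length(p) != length(q)) stop("mismatched histogram lengths")
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log2(a[i] / b[i]))
  }
  d <- kl(p, m) / 2 + kl(q, m) / 2
  d <- min(max(d, 0), 1)  # clip round-off
  if (distance) sqrt(d) else d
}

#' Signal-switch transition experiment
#'
#' Equilibrates an ensemble under `cond_from` (burn-in), switches the
#' extracellular signals instantaneously at t = 0, and records density
#' snapshots until the horizon. TF copies bound to a withdrawn signal
#' remain bound until they unbind.
#'
#' @inheritParams simulate_ensemble
#' @param cond_from,cond_to conditions (objects or labels).
#' @param snapshot_times increasing times from the switch (default
#'   `seq(0, 30, by = 0.25)`).
#' @param burn equilibration time under `cond_from` (default 50).
#' @return A `pdmp_transition`: list with `times`, `snapshots` (one
#'   `n_paths x genes` matrix per time), `cond_from`, `cond_to`, `final`
#'   (last snapshot).
#' @export
run_transition <- function(top, params, cond_from, cond_to, n_paths,
                           snapshot_times = seq(0, 30, by = 0.25),
                           burn = 50, seed = 1L) {
  if (is.character(cond_from)) cond_from <- parse_condition(cond_from)
  if (is.character(cond_to)) cond_to <- parse_condition(cond_to)
  net <- compile_net(top, params)
  presence <- rbind(condition_presence(top, cond_from),
                    condition_presence(top, cond_to))
  durations <- c(burn, max(snapshot_times))
  ens <- run_engine(net, presence, durations, snapshot_times, n_paths, seed,
                    FALSE, NULL, cond_to, params, top)
  snaps <- attr(ens, "snapshots")
  structure(list(times = snaps$times, snapshots = snaps$states,
                 cond_from = cond_from$label, cond_to = cond_to$label,
                 final = snaps$states[[length(snaps$states)]],
                 params = params, n_paths = n_paths, seed = seed),
            class = "pdmp_transition")
}

#' Transition time from a snapshot series
#'
#' Computes, for every snapshot, the Jensen-Shannon divergence between each
#' TF's instantaneous marginal and its final stationary marginal, and
#' returns the first snapshot time at which all TF divergences are below
#' the threshold. If the threshold is never met the horizon is returned
#' with attribute `censored = TRUE`.
#'
#' @param series a `pdmp_transition`.
#' @param final the stationary reference under `cond_to`: a
#'   `pdmp_ensemble`, a matrix, or a list of `pdmp_marginal` (one per
#'   gene). Defaults to the last snapshot of `series`.
#' @param cfg an [analysis_config()].
#' @return Scalar time; attributes `jsd` (matrix times x genes) and
#'   `censored`.
#' @export
transition_time <- function(series, final = NULL, cfg = analysis_config()) {
  gs <- colnames(series$snapshots[[1L]])
  if (is.null(final)) final <- series$final
  final_marg <- if (is.list(final) && !is.data.frame(final) &&
                    inherits(final[[1L]], "pdmp_marginal")) {
    stats::setNames(final, vapply(final, `[[`, "", "gene"))
  } else {
    stats::setNames(lapply(gs, function(g)
      marginal_histogram(final, g, cfg$bins, cfg$xlim)), gs)
  }
  jsd <- matrix(NA_real_, length(series$times), length(gs),
                dimnames = list(NULL, gs))
  for (i in seq_along(series$times)) {
    for (g in gs) {
      m <- marginal_histogram(series$snapshots[[i]], g, cfg$bins, cfg$xlim)
      jsd[i, g] <- js_divergence(m, final_marg[[g]],
                                 distance = cfg$use_distance)
    }
  }
  ok <- apply(jsd < cfg$jsd_threshold, 1L, all)
  idx <- which(ok)[1L]
  censored <- is.na(idx)
  t_out <- if (censored) series$times[length(series$times)]
           else series$times[idx]
  structure(t_out, jsd = jsd, censored = censored)
}

#' PCA attractor landscape
#'
#' Fits principal components on the mean-centered reference ensemble only
#' (no per-gene scaling: all densities share the non-dimensional (0,1)
#' scale) and projects every ensemble with the reference's centering and
#' loadings. Projected point clouds are binned on a shared grid into 2-D
#' probability landscapes.
#'
#' @param reference a `pdmp_ensemble` (the baseline condition).
#' @param others named list of ensembles to project.
#' @param grid_n grid cells per axis for the landscape densities.
#' @return A `pdmp_landscape`: list with `rotation`, `center`, `sdev`,
#'   `scores` (named list of n x 2 matrices, reference first), `density`
#'   (named list of grid_n x grid_n cell probabilities), `grid` (axis
#'   break points).
#' @export
pca_landscape <- function(reference, others = list(), grid_n = 50L) {
  if (nrow(reference) <= ncol(reference))
    stop("reference ensemble needs more paths than genes")
  for (o in others)
    if (!identical(colnames(o), colnames(reference)))
      stop("ensembles share neither gene set nor ordering")
  pc <- stats::prcomp(reference, center = TRUE, scale. = FALSE)
  project <- function(e)
    scale(unclass(e), center = pc$center, scale = FALSE) %*%
      pc$rotation[, 1:2]
  ref_label <- attr(reference, "condition")
  if (is.null(ref_label)) ref_label <- "reference"
  scores <- c(stats::setNames(list(project(reference)), ref_label),
              lapply(others, project))
  all_pts <- do.call(rbind, scores)
  gx <- seq(min(all_pts[, 1]), max(all_pts[, 1]), length.out = grid_n + 1L)
  gy <- seq(min(all_pts[, 2]), max(all_pts[, 2]), length.out = grid_n + 1L)
  dens <- lapply(scores, function(s) {
    ix <- findInterval(s[, 1], gx, rightmost.closed = TRUE, all.inside = TRUE)
    iy <- findInterval(s[, 2], gy, rightmost.closed = TRUE, all.inside = TRUE)
    m <- matrix(0, grid_n, grid_n)
    for (k in seq_len(nrow(s))) m[ix[k], iy[k]] <- m[ix[k], iy[k]] + 1
    m / nrow(s)
  })
  structure(list(rotation = pc$rotation, center = pc$center, sdev = pc$sdev,
                 scores = scores, density = dens,
                 grid = list(x = gx, y = gy)),
            class = "pdmp_landscape")
}

#' Occupied landscape area
#'
#' A reproducible proxy for attractor size: the number of grid cells whose
#' probability exceeds a fraction of the *reference* landscape's maximum
#' (default 1%).
#'
#' @param landscape a `pdmp_landscape`.
#' @param frac threshold fraction of the reference density maximum.
#' @return Named integer vector of occupied cell counts per ensemble.
#' @export
occupied_area <- function(landscape, frac = 0.01) {
  thr <- frac * max(landscape$density[[1L]])
  vapply(landscape$density, function(d) sum(d > thr), integer(1))
}

#' Pairwise TF correlations across an ensemble
#'
#' Sample Pearson correlation of (x_i, x_j) across paths; unit diagonal,
#' symmetric. Genes with zero variance get `NA` rows/columns (recorded,
#' not an error).
#'
#' @param ensemble a `pdmp_ensemble` with at least two paths.
#' @return Symmetric genes x genes matrix.
#' @export
pairwise_correlations <- function(ensemble) {
  if (nrow(ensemble) < 2L) stop("ensemble must hold at least two paths")
  v <- apply(ensemble, 2L, stats::var)
  m <- suppressWarnings(stats::cor(unclass(ensemble)))
  m[v == 0, ] <- NA_real_
  m[, v == 0] <- NA_real_
  diag(m) <- ifelse(v == 0, NA_real_, 1)
  m
}
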