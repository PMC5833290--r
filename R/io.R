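#' Convert non-dimensional time to physical hours
#'
#' The non-dimensional clock runs in units of the TF degradation rate
#' gamma, so a duration `t_nd` corresponds to `t_nd / gamma_physical`
#' hours. For stable pluripotency factors (half-life of order 8 h,
#' `gamma ~ 1/8` per hour), a simulated course of 30 time units spans 240
#' hours.
#'
#' @param t_nd non-dimensional time(s).
#' @param gamma_physical degradation rate in 1/hour (> 0).
#' @return Time in hours.
#' @export
to_physical_time <- function(t_nd, gamma_physical) {
  if (!is.numeric(gamma_physical) || any(gamma_physical <= 0))
    stop("gamma_physical must be positive")
  t_nd / gamma_physical
}

#' Write / read an ensemble as TSV with a JSON manifest
#'
#' The TSV holds one row per path and one column per gene; the sidecar
#' `<path>.json` records everything needed to reproduce the ensemble
#' (condition, parameters, horizon, seed, engine, package version).
#'
#' @param ensemble a `pdmp_ensemble`.
#' @param path output TSV path.
#' @return `write_ensemble`: `path`, invisibly. `read_ensemble`: a
#'   `pdmp_ensemble` (without promoter occupancy, which is not serialized).
#' @export
write_ensemble <- function(ensemble, path) {
  m <- unclass(ensemble)
  df <- as.data.frame(m)
  con <- file(path, "wb")
  writeLines(paste(colnames(m), collapse = "\t"), con, sep = "\n")
  writeLines(apply(df, 1L, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = "\t")),
    con, sep = "\n")
  close(con)
  p <- attr(ensemble, "params")
  manifest <- list(condition = attr(ensemble, "condition"),
                   time = attr(ensemble, "time"),
                   seed = attr(ensemble, "seed"),
                   engine = attr(ensemble, "engine") %||% "pdmp",
                   omega = attr(ensemble, "omega"),
                   n_paths = nrow(m),
                   params = unclass(p),
                   package_version = as.character(utils::packageVersion("pdmpnet")))
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df)
  man_path <- paste0(path, ".json")
  man <- if (file.exists(man_path)) jsonlite::fromJSON(man_path) else list()
  params <- if (!is.null(man$params)) do.call(model_params, man$params) else NULL
  structure(m, class = c("pdmp_ensemble", class(m)),
            condition = man$condition, time = man$time, seed = man$seed,
            engine = man$engine, params = params)
}

#' Built-in fixture models with analytic oracles
#'
#' Small models whose stationary laws are known in closed form, used for
#' engine validation:
#' \describe{
#'   \item{constitutive}{one unregulated gene; the density flows
#'     deterministically to `alpha_max/gamma` with no promoter events, and
#'     the individual-based stationary copy number is Poisson with mean
#'     `Omega * alpha_max / gamma`.}
#'   \item{telegraph}{one gene with a single promoter site (N = 1) bound by
#'     one constantly present activating signal: the classic two-state
#'     gene. Its PDMP stationary density is Beta(k_on, k_off) on (0, 1).}
#'   \item{toggle}{two mutually repressing genes (both also
#'     self-activating), a minimal bistable switch; no closed-form oracle.}
#'   \item{mesc}{the packaged 12-gene pluripotency network.}
#' }
#'
#' @param name fixture name.
#' @param params optional `pdmp_params` override.
#' @return List with `topology`, `params`, `condition`, and for fixtures
#'   with an oracle a `stationary` descriptor (e.g.
#'   `list(law = "beta", shape1 = k_on, shape2 = k_off)`).
#' @export
fixture_model <- function(name = c("constitutive", "telegraph", "toggle",
                                   "mesc"),
                          params = NULL) {
  name <- match.arg(name)
  if (name == "constitutive") {
    top <- topology(data.frame(id = "A", type = "gene"),
                    data.frame(source = character(0), target = character(0),
                               sign = character(0)))
    params <- params %||% model_params(n_sites = 1L, k_on = 0, k_off = 0,
                                       alpha_m = 0)
    return(list(topology = top, params = params,
                condition = signal_condition(),
                stationary = list(law = "point", at = params$alpha_max /
                                    params$gamma)))
  }
  if (name == "telegraph") {
    top <- topology(
      data.frame(id = c("A", "S"), type = c("gene", "signal")),
      data.frame(source = "S", target = "A", sign = "activating"))
    params <- params %||% model_params(n_sites = 1L, k_on = 2, k_off = 3,
                                       alpha_m = 0)
    return(list(topology = top, params = params,
                condition = signal_condition(present = "S", label = "S"),
                stationary = list(law = "beta",
                                  shape1 = params$k_on / params$gamma,
                                  shape2 = params$k_off / params$gamma)))
  }
  if (name == "toggle") {
    top <- topology(
      data.frame(id = c("A", "B"), type = c("gene", "gene")),
      data.frame(source = c("A", "B", "B", "A"),
                 target = c("A", "B", "A", "B"),
                 sign = c("activating", "activating", "repressing",
                          "repressing")))
    params <- params %||% model_params(n_sites = 2L, k_on = 10, k_off = 1,
                                       alpha_m = 0.1)
    return(list(topology = top, params = params,
                condition = signal_condition(), stationary = NULL))
  }
  list(topology = mesc_topology(), params = params %||% regime_params(),
       condition = parse_condition("LIF+2i"), stationary = NULL)
}
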