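#' Construct a network topology
#'
#' A topology is the Boolean-level description of a gene-regulatory network:
#' a set of typed nodes (genes, which are simulated, and signals, which are
#' externally imposed inputs) and signed directed edges. Edge targets must be
#' genes; sources may be genes or signals.
#'
#' @param nodes data.frame with columns `id` (character) and
#'   `type` (`"gene"` or `"signal"`).
#' @param edges data.frame with columns `source`, `target`, `sign`
#'   (`"activating"` or `"repressing"`).
#' @return An object of class `pdmp_topology`.
#' @export
topology <- function(nodes, edges) {
  nodes <- data.frame(id = as.character(nodes$id),
                      type = as.character(nodes$type),
                      stringsAsFactors = FALSE)
  edges <- data.frame(source = as.character(edges$source),
                      target = as.character(edges$target),
                      sign = as.character(edges$sign),
                      stringsAsFactors = FALSE)
  obj <- structure(list(nodes = nodes, edges = edges), class = "pdmp_topology")
  validate_topology(obj)
}

validate_topology <- function(top) {
  nodes <- top$nodes
  edges <- top$edges
  if (anyDuplicated(nodes$id))
    stop("duplicate node id(s): ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  bad_type <- setdiff(unique(nodes$type), c("gene", "signal"))
  if (length(bad_type))
    stop("unknown node type(s): ", paste(bad_type, collapse = ", "))
  bad_sign <- setdiff(unique(edges$sign), c("activating", "repressing"))
  if (length(bad_sign))
    stop("unknown edge sign(s): ", paste(bad_sign, collapse = ", "))
  if (nrow(edges)) {
    unknown <- setdiff(c(edges$source, edges$target), nodes$id)
    if (length(unknown))
      stop("edge references unknown node(s): ", paste(unknown, collapse = ", "))
    tgt_type <- nodes$type[match(edges$target, nodes$id)]
    if (any(tgt_type != "gene")) {
      i <- which(tgt_type != "gene")[1L]
      stop("edge ", edges$source[i], " -> ", edges$target[i],
           " targets a signal node; only genes can be regulated")
    }
    key <- paste(edges$source, edges$target)
    if (anyDuplicated(key))
      stop("duplicate edge(s): ", paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  top
}

#' @export
print.pdmp_topology <- function(x, ...) {
  cat("<pdmp_topology> ", sum(x$nodes$type == "gene"), " genes, ",
      sum(x$nodes$type == "signal"), " signals, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Gene and signal identifiers of a topology
#'
#' @param top a `pdmp_topology`.
#' @return Character vector of ids, in file order.
#' @export
genes <- function(top) top$nodes$id[top$nodes$type == "gene"]

#' @rdname genes
#' @export
signals <- function(top) top$nodes$id[top$nodes$type == "signal"]

#' Read a topology file
#'
#' Accepts either the two-section TSV format (a `#nodes` section of
#' `id<TAB>gene|signal` lines followed by a `#edges` section of
#' `source<TAB>target<TAB>activating|repressing` lines; other lines starting
#' with `#` are comments) or an equivalent JSON object with `nodes` and
#' `edges` members. The format is detected from the file extension
#' (`.json` vs anything else).
#'
#' @param path file path.
#' @return A validated `pdmp_topology`.
#' @export
load_topology <- function(path) {
  if (!file.exists(path)) stop("topology file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::fromJSON(path)
    return(topology(obj$nodes, obj$edges))
  }
  lines <- readLines(path, warn = FALSE)
  section <- NA_character_
  nodes <- list(); edges <- list()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) next
    if (ln == "#nodes") { section <- "nodes"; next }
    if (ln == "#edges") { section <- "edges"; next }
    if (startsWith(ln, "#")) next  # comment
    if (is.na(section))
      stop("parse error at line ", i, ": content before #nodes/#edges section")
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (section == "nodes") {
      if (length(f) != 2L)
        stop("parse error at line ", i, ": expected 'id<TAB>gene|signal'")
      nodes[[length(nodes) + 1L]] <- f
    } else {
      if (length(f) != 3L)
        stop("parse error at line ", i,
             ": expected 'source<TAB>target<TAB>activating|repressing'")
      edges[[length(edges) + 1L]] <- f
    }
  }
  if (!length(nodes)) stop("no #nodes section in ", path)
  nd <- do.call(rbind, nodes)
  eg <- if (length(edges)) do.call(rbind, edges) else
    matrix(character(0), 0, 3)
  topology(
    data.frame(id = nd[, 1], type = nd[, 2], stringsAsFactors = FALSE),
    data.frame(source = eg[, 1], target = eg[, 2], sign = eg[, 3],
               stringsAsFactors = FALSE)
  )
}

#' Write a topology file
#'
#' Emits the canonical two-section TSV format (or JSON for `.json` paths).
#' `load_topology(write_topology(top, f))` reproduces `top` exactly, and
#' re-writing the loaded object is byte-identical.
#'
#' @param top a `pdmp_topology`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_topology <- function(top, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(nodes = top$nodes, edges = top$edges), path,
                         dataframe = "columns")
    return(invisible(path))
  }
  con <- file(path, "wb")  # binary mode: LF newlines on every platform
  on.exit(close(con))
  writeLines(c("#nodes",
               paste(top$nodes$id, top$nodes$type, sep = "\t"),
               "#edges",
               paste(top$edges$source, top$edges$target, top$edges$sign,
                     sep = "\t")),
             con, sep = "\n")
  invisible(path)
}

#' Partition each gene's regulators by sign
#'
#' For gene *i* the union of the two sets is its regulator set S_i: the
#' transcription factors (and signals) that compete for its promoter sites.
#'
#' @param top a `pdmp_topology`.
#' @return Named list over genes; each element is
#'   `list(activators = character, repressors = character)`.
#' @export
regulator_sets <- function(top) {
  gs <- genes(top)
  out <- lapply(gs, function(g) {
    e <- top$edges[top$edges$target == g, , drop = FALSE]
    list(activators = sort(e$source[e$sign == "activating"]),
         repressors = sort(e$source[e$sign == "repressing"]))
  })
  names(out) <- gs
  out
}

#' Promoter configuration to production activity
#'
#' The molecular logic shared by every gene. With N promoter sites:
#' a gene regulated only by activators is ON iff all N sites are bound by
#' activators, else OFF; a gene regulated only by repressors is OFF iff all
#' N sites are bound by repressors, else ON; a gene with both kinds of
#' regulator is ON when fully activator-bound, OFF when fully
#' repressor-bound, and MEDIUM otherwise. A gene with no regulators is
#' constitutively ON. The associated production rates are `alpha_max`,
#' `alpha_m` and 0 (non-dimensional).
#'
#' @param gene_id gene identifier.
#' @param occupancy named integer vector: sites bound per regulator. Only
#'   regulators of `gene_id` may appear; the counts must be non-negative and
#'   sum to at most `params$n_sites`.
#' @param regs output of [regulator_sets()].
#' @param params a [model_params()] object.
#' @return `list(level = "OFF"|"MEDIUM"|"ON", rate = <numeric>)`.
#' @export
production_activity <- function(gene_id, occupancy, regs, params) {
  rs <- regs[[gene_id]]
  if (is.null(rs)) stop("unknown gene: ", gene_id)
  occupancy <- occupancy[occupancy != 0]
  if (length(occupancy)) {
    if (is.null(names(occupancy)) ||
        !all(names(occupancy) %in% c(rs$activators, rs$repressors)))
      stop("occupancy of ", gene_id, " references a non-regulator")
    if (any(occupancy < 0) || sum(occupancy) > params$n_sites)
      stop("invalid occupancy for ", gene_id)
  }
  n_act <- sum(occupancy[names(occupancy) %in% rs$activators])
  n_rep <- sum(occupancy[names(occupancy) %in% rs$repressors])
  has_act <- length(rs$activators) > 0L
  has_rep <- length(rs$repressors) > 0L
  N <- params$n_sites
  level <-
    if (!has_act && !has_rep) "ON"           # unregulated: constitutive
    else if (has_act && !has_rep) { if (n_act == N) "ON" else "OFF" }
    else if (!has_act && has_rep) { if (n_rep == N) "OFF" else "ON" }
    else if (n_act == N) "ON"
    else if (n_rep == N) "OFF"
    else "MEDIUM"
  rate <- switch(level, ON = params$alpha_max, MEDIUM = params$alpha_m, OFF = 0)
  list(level = level, rate = rate)
}

#' Kinetic model parameters (non-dimensional)
#'
#' Time is measured in units of the TF degradation rate gamma and
#' concentration in units of `alpha_max / gamma`, so after
#' non-dimensionalization `alpha_max = gamma = 1`, TF densities live in
#' (0, 1), and four free parameters remain: the number of promoter sites per
#' gene `n_sites` (N), the per-site binding rate constant `k_on`, the
#' per-bound-copy unbinding rate `k_off`, and the MEDIUM production rate
#' `alpha_m`. `omega` is the population scale translating densities to copy
#' numbers in the individual-based model (default 1e4).
#'
#' @param n_sites positive integer, promoter sites per gene.
#' @param k_on,k_off non-negative binding/unbinding rate constants.
#' @param alpha_m MEDIUM production rate in `[0, alpha_max]`.
#' @param alpha_max,gamma fixed at 1 in non-dimensional mode.
#' @param omega positive integer population scale.
#' @return An object of class `pdmp_params`.
#' @export
model_params <- function(n_sites = 2L, k_on = 16, k_off = 1.5,
                         alpha_m = 0.01, alpha_max = 1, gamma = 1,
                         omega = 1e4L) {
  stopifnot(n_sites >= 1, n_sites == as.integer(n_sites),
            k_on >= 0, k_off >= 0,
            alpha_m >= 0, alpha_m <= alpha_max,
            alpha_max > 0, gamma > 0, omega >= 1)
  structure(list(n_sites = as.integer(n_sites), k_on = k_on, k_off = k_off,
                 alpha_m = alpha_m, alpha_max = alpha_max, gamma = gamma,
                 omega = omega),
            class = "pdmp_params")
}

#' @export
print.pdmp_params <- function(x, ...) {
  cat(sprintf("<pdmp_params> N=%d k_on=%g k_off=%g alpha_m=%g (alpha_max=%g gamma=%g Omega=%g)\n",
              x$n_sites, x$k_on, x$k_off, x$alpha_m, x$alpha_max, x$gamma,
              x$omega))
  invisible(x)
}

#' Extracellular signal condition
#'
#' The culture condition is a presence/absence assignment to the three
#' signal inputs LIF, CH and PD. "2i" denotes CH + PD. When `label` is
#' omitted a canonical one is derived ("LIF+2i", "2i", "LIF+CH", "LIF+PD",
#' "LIF", "CH", "PD", "None").
#'
#' @param lif,ch,pd logical, signal present?
#' @param present additional present signal ids, for topologies whose
#'   signals are not named LIF/CH/PD.
#' @param label optional condition label.
#' @return An object of class `pdmp_condition`.
#' @export
signal_condition <- function(lif = FALSE, ch = FALSE, pd = FALSE,
                             present = character(0), label = NULL) {
  stopifnot(is.logical(lif), is.logical(ch), is.logical(pd),
            is.character(present))
  if (is.null(label)) {
    if (ch && pd) label <- if (lif) "LIF+2i" else "2i"
    else {
      parts <- c(c("LIF", "CH", "PD")[c(lif, ch, pd)], present)
      label <- if (length(parts)) paste(parts, collapse = "+") else "None"
    }
  }
  structure(list(lif = lif, ch = ch, pd = pd, present = present,
                 label = label),
            class = "pdmp_condition")
}

#' Presence (0/1) of a signal id under a condition
#'
#' @param sig signal id.
#' @param condition a `pdmp_condition`.
#' @return 1 if present, 0 otherwise.
#' @export
signal_density <- function(sig, condition) {
  as.numeric(switch(sig,
                    LIF = condition$lif, CH = condition$ch,
                    PD = condition$pd,
                    sig %in% condition$present))
}

#' Parse a condition label
#'
#' Inverse of the canonical labelling of [signal_condition()].
#' @param label e.g. `"LIF+2i"`, `"2i"`, `"None"`.
#' @return A `pdmp_condition`.
#' @export
parse_condition <- function(label) {
  parts <- if (identical(label, "None")) character(0)
           else strsplit(label, "+", fixed = TRUE)[[1L]]
  bad <- setdiff(parts, c("LIF", "CH", "PD", "2i"))
  if (length(bad)) stop("unknown signal(s) in condition label: ", label)
  signal_condition(lif = "LIF" %in% parts,
                   ch = "CH" %in% parts || "2i" %in% parts,
                   pd = "PD" %in% parts || "2i" %in% parts)
}

#' Standard condition sets
#'
#' `all_conditions()` returns the 8 combinations of the three signals;
#' `benchmark_conditions()` the 5 self-renewal-permissive cultures used as
#' benchmark columns (LIF+2i, 2i, LIF+CH, LIF+PD, LIF).
#'
#' @return List of `pdmp_condition` objects.
#' @export
all_conditions <- function() {
  lab <- c("LIF+2i", "2i", "LIF+CH", "LIF+PD", "LIF", "CH", "PD", "None")
  lapply(lab, parse_condition)
}

#' @rdname all_conditions
#' @export
benchmark_conditions <- function() {
  lapply(c("LIF+2i", "2i", "LIF+CH", "LIF+PD", "LIF"), parse_condition)
}

#' Packaged mESC pluripotency network and benchmark
#'
#' `mesc_topology()` loads the curated 12-gene / 3-signal naive-pluripotency
#' network (a reconstruction of the minimal program of Dunn et al. 2014;
#' see the file header in `inst/extdata/mesc_topology.tsv` for provenance).
#' `mesc_benchmark()` loads the matching 12x5 binary expression benchmark.
#'
#' @return A `pdmp_topology`, respectively an integer matrix with gene rows
#'   and condition columns.
#' @export
mesc_topology <- function() {
  load_topology(system.file("extdata", "mesc_topology.tsv",
                            package = "pdmpnet", mustWork = TRUE))
}

#' @rdname mesc_topology
#' @export
mesc_benchmark <- function() {
  path <- system.file("extdata", "mesc_benchmark.tsv",
                      package = "pdmpnet", mustWork = TRUE)
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1L]]
  m
}
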