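# Small topologies and utilities shared across tests. Everything is built
# in code; no stored fixtures beyond the packaged mESC files.

make_topology_file <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

minimal_topology_lines <- c(
  "#nodes", "A\tgene", "S\tsignal",
  "#edges", "S\tA\tactivating")

# one gene regulated by two activators (X, Y) and one repressor (Z),
# all three constitutive genes so their activity is always ON
mixed_gene_topology <- function() {
  topology(
    data.frame(id = c("G", "X", "Y", "Z"), type = "gene"),
    data.frame(source = c("X", "Y", "Z"), target = "G",
               sign = c("activating", "activating", "repressing")))
}

# enumerate all occupancy multisets of r regulators over N sites
enumerate_occupancies <- function(reg_names, N) {
  r <- length(reg_names)
  grid <- expand.grid(rep(list(0:N), r))
  grid <- grid[rowSums(grid) <= N, , drop = FALSE]
  lapply(seq_len(nrow(grid)), function(i) {
    v <- as.integer(grid[i, ])
    names(v) <- reg_names
    v
  })
}

# manual hazard object for channel-level tests
hazard_object <- function(const_part, trans_part,
                          kind = rep("bind", length(const_part))) {
  structure(list(a_coef = sum(const_part), c_coef = sum(trans_part),
                 channels = data.frame(kind = kind,
                                       gene = paste0("g", seq_along(const_part)),
                                       regulator = "r",
                                       const_part = const_part,
                                       trans_part = trans_part,
                                       stringsAsFactors = FALSE)),
            class = "pdmp_hazard")
}

mean_jsd_between <- function(ens_a, ens_b, bins = 20) {
  gs <- colnames(ens_a)
  vapply(gs, function(g) {
    js_divergence(marginal_histogram(ens_a, g, bins),
                  marginal_histogram(ens_b, g, bins))
  }, numeric(1))
}
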