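test_that("a minimal topology file parses into one gene, one signal, one edge", {
  f <- make_topology_file(minimal_topology_lines)
  top <- load_topology(f)
  expect_s3_class(top, "pdmp_topology")
  expect_identical(genes(top), "A")
  expect_identical(signals(top), "S")
  expect_identical(nrow(top$edges), 1L)
})

test_that("the packaged mESC network matches its documented anchors", {
  top <- mesc_topology()
  expect_length(genes(top), 12)
  expect_setequal(signals(top), c("LIF", "CH", "PD"))
  regs <- regulator_sets(top)
  # Nanog is regulated by Klf2, Sox2 and MEK/ERK
  expect_setequal(c(regs$Nanog$activators, regs$Nanog$repressors),
                  c("Klf2", "Sox2", "MEKERK"))
  expect_identical(regs$Nanog$repressors, "MEKERK")
  # exactly four genes carry mixed (activator + repressor) regulation
  mixed <- names(Filter(function(r)
    length(r$activators) > 0 && length(r$repressors) > 0, regs))
  expect_setequal(mixed, c("Tfcp2l1", "Esrrb", "Nanog", "Oct4"))
  # signal wiring: LIF -> Stat3, PD -| MEKERK
  expect_identical(regs$Stat3$activators, "LIF")
  expect_identical(regs$MEKERK$repressors, "PD")
})

test_that("malformed or inconsistent topology files are rejected with context", {
  f <- make_topology_file(c("#nodes", "A\tgene", "badline-without-tab",
                            "#edges"))
  expect_error(load_topology(f), "line 3")
  f <- make_topology_file(c("#nodes", "A\tgene", "S\tsignal",
                            "#edges", "A\tS\tactivating"))
  expect_error(load_topology(f), "targets a signal")
  f <- make_topology_file(c("#nodes", "A\tgene",
                            "#edges", "B\tA\tactivating"))
  expect_error(load_topology(f), "unknown node")
  f <- make_topology_file(c("#nodes", "A\tgene", "B\tgene", "#edges",
                            "A\tB\tactivating", "A\tB\tactivating"))
  expect_error(load_topology(f), "duplicate edge")
  expect_error(load_topology(tempfile()), "not found")
})

test_that("topology TSV and JSON round-trips are exact", {
  top <- mesc_topology()
  f <- tempfile(fileext = ".tsv")
  write_topology(top, f)
  top2 <- load_topology(f)
  expect_identical(top2$nodes, top$nodes)
  expect_identical(top2$edges, top$edges)
  f2 <- tempfile(fileext = ".tsv")
  write_topology(top2, f2)
  expect_identical(readBin(f, "raw", file.size(f)),
                   readBin(f2, "raw", file.size(f2)))  # byte-exact
  fj <- tempfile(fileext = ".json")
  write_topology(top, fj)
  topj <- load_topology(fj)
  expect_identical(topj$edges, top$edges)
})

test_that("regulator sets partition in-edges by sign", {
  regs <- regulator_sets(mixed_gene_topology())
  expect_setequal(regs$G$activators, c("X", "Y"))
  expect_identical(regs$G$repressors, "Z")
  expect_identical(regs$X$activators, character(0))
  expect_identical(regs$X$repressors, character(0))
})

test_that("the molecular logic maps promoter configurations to activity", {
  top <- mixed_gene_topology()
  regs <- regulator_sets(top)
  p <- model_params(n_sites = 2L, k_on = 1, k_off = 1, alpha_m = 0.25)
  # mixed gene: fully activator-bound -> ON at alpha_max
  expect_identical(
    production_activity("G", c(X = 2L), regs, p),
    list(level = "ON", rate = 1))
  # one activator + one repressor -> MEDIUM at alpha_m
  expect_identical(
    production_activity("G", c(X = 1L, Z = 1L), regs, p),
    list(level = "MEDIUM", rate = 0.25))
  # fully repressor-bound -> OFF
  expect_identical(
    production_activity("G", c(Z = 2L), regs, p)$rate, 0)
  # unregulated gene: constitutively ON
  expect_identical(production_activity("X", integer(0), regs, p)$level, "ON")
  # occupancy naming a non-regulator is a contract violation
  expect_error(production_activity("G", c(Q = 1L), regs, p), "non-regulator")
  expect_error(production_activity("G", c(X = 3L), regs, p), "invalid")
})

test_that("single-sign genes follow the all-or-nothing rule", {
  top <- topology(
    data.frame(id = c("GA", "GR", "X", "Z"), type = "gene"),
    data.frame(source = c("X", "Z"), target = c("GA", "GR"),
               sign = c("activating", "repressing")))
  regs <- regulator_sets(top)
  p <- model_params(n_sites = 2L, alpha_m = 0.3)
  # activator-only: OFF unless all N sites bound by activators
  expect_identical(production_activity("GA", c(X = 1L), regs, p)$rate, 0)
  expect_identical(production_activity("GA", c(X = 2L), regs, p)$rate, 1)
  # repressor-only: ON unless all N sites bound by repressors
  expect_identical(production_activity("GR", integer(0), regs, p)$rate, 1)
  expect_identical(production_activity("GR", c(Z = 2L), regs, p)$rate, 0)
})

test_that("occupancy enumeration matches the combinatorial count and logic", {
  for (N in 1:3) for (r_act in 1:2) for (r_rep in 1:2) {
    r <- r_act + r_rep
    acts <- paste0("A", seq_len(r_act))
    reps <- paste0("R", seq_len(r_rep))
    ids <- c("G", acts, reps)
    top <- topology(
      data.frame(id = ids, type = "gene"),
      data.frame(source = c(acts, reps), target = "G",
                 sign = rep(c("activating", "repressing"), c(r_act, r_rep))))
    regs <- regulator_sets(top)
    p <- model_params(n_sites = N, alpha_m = 0.5)
    occs <- enumerate_occupancies(c(acts, reps), N)
    expect_length(occs, choose(N + r, r))
    lv <- vapply(occs, function(o)
      production_activity("G", o, regs, p)$level, character(1))
    on_idx <- vapply(occs, function(o)
      sum(o[acts]) == N, logical(1))
    off_idx <- vapply(occs, function(o)
      sum(o[reps]) == N, logical(1))
    expect_identical(lv == "ON", on_idx)
    expect_identical(lv == "OFF", off_idx)
  }
})

test_that("activator-for-repressor swaps never decrease the production rate", {
  top <- mixed_gene_topology()
  regs <- regulator_sets(top)
  for (N in 1:3) {
    p <- model_params(n_sites = N, alpha_m = 0.4)
    for (occ in enumerate_occupancies(c("X", "Y", "Z"), N)) {
      if (occ[["Z"]] == 0) next
      swapped <- occ + c(X = 1L, Y = 0L, Z = -1L)
      expect_gte(production_activity("G", swapped, regs, p)$rate,
                 production_activity("G", occ, regs, p)$rate)
    }
  }
})

test_that("conditions label and parse canonically", {
  expect_identical(signal_condition(TRUE, TRUE, TRUE)$label, "LIF+2i")
  expect_identical(signal_condition(FALSE, TRUE, TRUE)$label, "2i")
  expect_identical(signal_condition()$label, "None")
  co <- parse_condition("LIF+PD")
  expect_true(co$lif && co$pd && !co$ch)
  expect_identical(vapply(all_conditions(), `[[`, "", "label"),
                   c("LIF+2i", "2i", "LIF+CH", "LIF+PD", "LIF", "CH", "PD",
                     "None"))
  expect_error(parse_condition("LIF+XX"), "unknown signal")
})

test_that("the packaged benchmark matrix is a labelled 12x5 binary pattern", {
  b <- mesc_benchmark()
  expect_identical(dim(b), c(12L, 5L))
  expect_true(all(b %in% 0:1))
  expect_identical(colnames(b), c("LIF+2i", "2i", "LIF+CH", "LIF+PD", "LIF"))
  expect_setequal(rownames(b), genes(mesc_topology()))
  # the pluripotency triad is expressed under every benchmark condition
  expect_true(all(b[c("Nanog", "Oct4", "Sox2"), ] == 1))
})
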