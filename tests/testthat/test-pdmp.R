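test_that("flow reproduces the closed-form relaxation exactly", {
  expect_equal(flow(0, 1, log(2)), 0.5)
  expect_equal(flow(0.37, 0.37, 123), 0.37)          # fixed point
  expect_equal(flow(1, 0, 1), exp(-1))
  expect_equal(flow(0.2, 0.8, 2, gamma = 2), 0.4 + (0.2 - 0.4) * exp(-4))
  expect_error(flow(0, 1, -0.1), "non-negative")
})

test_that("hazard_summary enumerates channels with the stated rates", {
  f <- make_topology_file(minimal_topology_lines)
  top <- load_topology(f)
  p <- model_params(n_sites = 2L, k_on = 5, k_off = 3)
  co <- signal_condition(present = "S", label = "S")
  # unbound promoter, constant activator at density 1: one binding channel,
  # hazard N * k_on, no transient part
  st <- system_state(top, co)
  h <- hazard_summary(st, p, top)
  expect_identical(nrow(h$channels), 1L)
  expect_identical(h$channels$kind, "bind")
  expect_equal(h$a_coef, 2 * 5)
  expect_equal(h$c_coef, 0)
  # fully bound: a single unbinding channel at N * k_off
  st2 <- system_state(top, co, promoter = list(A = c(S = 2L)))
  h2 <- hazard_summary(st2, p, top)
  expect_identical(h2$channels$kind, "unbind")
  expect_equal(h2$a_coef, 2 * 3)
})

test_that("binding against a relaxing gene density splits into constant and transient parts", {
  # regulator R is constitutive (alpha = 1) and currently at x = 0.2, so
  # x_R(t) = 1 + (0.2 - 1) e^-t; the binding hazard inherits that split
  top <- topology(
    data.frame(id = c("G", "R"), type = "gene"),
    data.frame(source = "R", target = "G", sign = "activating"))
  p <- model_params(n_sites = 2L, k_on = 5, k_off = 3)
  st <- system_state(top, signal_condition(), densities = c(G = 0, R = 0.2))
  h <- hazard_summary(st, p, top)
  bind <- h$channels[h$channels$kind == "bind" & h$channels$gene == "G", ]
  expect_equal(bind$const_part, 2 * 5 * 1)
  expect_equal(bind$trans_part, 2 * 5 * (0.2 - 1))
  lam <- function(t) h$a_coef + h$c_coef * exp(-t)
  expect_true(all(lam(seq(0, 10, by = 0.01)) >= 0))
})

test_that("the closed-form integrated hazard agrees with numerical quadrature", {
  set.seed(11)
  top <- mesc_topology()
  p <- regime_params("intermediate")
  co <- parse_condition("LIF+2i")
  for (rep in 1:5) {
    dens <- stats::setNames(runif(12), genes(top))
    st <- system_state(top, co, densities = dens)
    h <- hazard_summary(st, p, top)
    lam <- function(t) h$a_coef + h$c_coef * exp(-t)
    for (t1 in c(0.3, 1.7, 6)) {
      quad <- stats::integrate(lam, 0, t1, rel.tol = 1e-13)$value
      expect_equal(integrated_hazard(h, t1), quad, tolerance = 1e-10)
    }
  }
})

test_that("waiting-time inversion is exact and both routes agree", {
  # constant hazard: plain exponential
  expect_equal(sample_event_time(hazard_object(2, 0), 1), 0.5)
  # saturating cumulative hazard: no event
  expect_identical(sample_event_time(hazard_object(0, 1), 2), Inf)
  # a = c = 1, e = 1: root of t + 1 - exp(-t) = 1 is the omega constant
  t_star <- sample_event_time(hazard_object(1, 1), 1)
  expect_equal(t_star, 0.5671433, tolerance = 1e-6)
  expect_error(sample_event_time(hazard_object(1, 1), -1), "positive")

  set.seed(42)
  for (i in 1:200) {
    a <- runif(1, 0, 50)
    cc <- runif(1, -a, 50)        # keeps Lambda(t) >= 0
    if (a == 0 && cc <= 0) next
    e <- rexp(1)
    h <- hazard_object(a, cc)
    t_lam <- sample_event_time(h, e, method = "lambert")
    t_bis <- sample_event_time(h, e, method = "bisection")
    t_cpp <- pdmpnet:::cpp_solve_tau(a, cc, e, 1)
    if (is.finite(t_lam)) {
      expect_equal(t_lam, t_bis, tolerance = 1e-9)
      expect_equal(t_lam, t_cpp, tolerance = 1e-9)
      expect_lt(abs(integrated_hazard(h, t_lam) - e), 1e-10 * max(1, e))
      expect_lt(abs(integrated_hazard(h, t_cpp) - e), 1e-10 * max(1, e))
    } else {
      expect_identical(t_bis, Inf)
      expect_identical(t_cpp, Inf)
    }
  }
})

test_that("sampled waiting times follow the law implied by the hazard", {
  h <- hazard_object(1.3, 0.7)
  set.seed(99)
  e <- rexp(1e5)
  tt <- sample_event_time(h, e)
  # inverse-transform consistency: F(t) = 1 - exp(-H(t))
  ks <- suppressWarnings(
    stats::ks.test(tt, function(q) 1 - exp(-integrated_hazard(h, q))))
  expect_gt(ks$p.value, 0.01)
  # monotone in the driving deviate
  ord <- order(e[1:1000])
  expect_true(!is.unsorted(tt[1:1000][ord]))
})

test_that("event selection is proportional to instantaneous hazards", {
  h <- hazard_object(c(3, 1), c(0, 0))
  expect_identical(select_event(h, 0.2, 0.74)$gene, "g1")
  expect_identical(select_event(h, 0.2, 0.76)$gene, "g2")
  h1 <- hazard_object(5, 0)
  expect_identical(select_event(h1, 1, 0.999)$gene, "g1")
  expect_error(select_event(hazard_object(0, 0), 1, 0.5), "zero")
  # Monte-Carlo selection frequencies match the hazard ratio within 3 SE
  h2 <- hazard_object(c(2, 0.5), c(1, 0))   # at t = 0.7
  t_ev <- 0.7
  lam <- h2$channels$const_part + h2$channels$trans_part * exp(-t_ev)
  p1 <- lam[1] / sum(lam)
  set.seed(5)
  u <- runif(2e4)
  got <- mean(vapply(u, function(ui)
    select_event(h2, t_ev, ui)$gene == "g1", logical(1)))
  expect_lt(abs(got - p1), 3 * sqrt(p1 * (1 - p1) / 2e4))
})

test_that("a constitutive gene produces an event-free exact path", {
  fx <- fixture_model("constitutive")
  path <- simulate_path(fx$topology, fx$params, fx$condition,
                        t_end = log(2), seed = 3)
  expect_identical(nrow(path$events), 0L)
  expect_equal(unname(path$final["A"]), 0.5)   # flow(0, 1, log 2)
})

test_that("ensembles are reproducible and reduce to single paths", {
  tg <- fixture_model("telegraph")
  e1 <- simulate_ensemble(tg$topology, tg$params, tg$condition, 50, 10, seed = 8)
  e2 <- simulate_ensemble(tg$topology, tg$params, tg$condition, 50, 10, seed = 8)
  expect_identical(unclass(e1)[, ], unclass(e2)[, ])
  e3 <- simulate_ensemble(tg$topology, tg$params, tg$condition, 50, 10, seed = 9)
  expect_false(identical(unclass(e1)[, ], unclass(e3)[, ]))
  p1 <- simulate_path(tg$topology, tg$params, tg$condition, 10, seed = 8)
  expect_equal(unname(p1$final["A"]), unname(e1[1L, "A"]))
})

test_that("telegraph stationary density matches the Beta(k_on, k_off) law", {
  tg <- fixture_model("telegraph")
  ens <- simulate_ensemble(tg$topology, tg$params, tg$condition,
                           n_paths = 1e4, t_end = 50, seed = 7)
  ks <- suppressWarnings(stats::ks.test(
    as.numeric(ens[, "A"]),
    function(q) stats::pbeta(q, tg$params$k_on, tg$params$k_off)))
  expect_gt(ks$p.value, 0.01)
  # and the matching histogram is close to the analytic bin masses
  hst <- marginal_histogram(ens, "A", bins = 20, xlim = c(0, 1))
  theo <- diff(stats::pbeta(hst$edges, tg$params$k_on, tg$params$k_off))
  expect_lt(max(abs(hst$mass - theo)), 0.02)
})

test_that("densities stay inside the non-dimensional unit interval", {
  top <- mesc_topology()
  p <- regime_params("slow")
  ens <- simulate_ensemble(top, p, parse_condition("LIF"), n_paths = 200,
                           t_end = 20, seed = 2,
                           snapshot_times = seq(0.5, 20, by = 0.5))
  expect_true(all(ens >= 0 & ens <= 1))
  for (s in attr(ens, "snapshots")$states)
    expect_true(all(s >= 0 & s <= 1))
})

test_that("stationary event counts scale linearly with the switching rates", {
  # telegraph stationary event flux is 2 k_on k_off / (k_on + k_off) per
  # unit time; scaling both rates by 10 must scale the windowed count by 10
  top <- fixture_model("telegraph")$topology
  co <- signal_condition(present = "S", label = "S")
  counts <- vapply(c(1, 10), function(f) {
    p <- model_params(n_sites = 1L, k_on = 2 * f, k_off = 3 * f)
    e_long <- simulate_ensemble(top, p, co, 400, t_end = 150, seed = 31)
    e_short <- simulate_ensemble(top, p, co, 400, t_end = 50, seed = 31)
    mean(attr(e_long, "n_events") - attr(e_short, "n_events"))
  }, numeric(1))
  expect_lt(abs(counts[2] / counts[1] - 10) / 10, 0.05)
  # absolute agreement with the analytic stationary flux, within 3 SE
  rate <- 2 * 2 * 3 / (2 + 3)
  expect_lt(abs(counts[1] - 100 * rate), 3 * sqrt(100 * rate / 400) * 3)
})

test_that("signal-removal-and-restoration returns to the same stationary law", {
  tg <- fixture_model("telegraph")
  co_on <- tg$condition
  co_off <- signal_condition(label = "None")
  direct <- simulate_ensemble(tg$topology, tg$params, co_on, 4000, 60, seed = 1)
  stage1 <- simulate_ensemble(tg$topology, tg$params, co_on, 4000, 50, seed = 2)
  stage2 <- simulate_ensemble(tg$topology, tg$params, co_off, 4000, 20, seed = 3,
                              init = stage1)
  stage3 <- simulate_ensemble(tg$topology, tg$params, co_on, 4000, 60, seed = 4,
                              init = stage2)
  expect_lt(mean_jsd_between(stage3, direct)[["A"]], 0.05)
  # and the withdrawn stage decays toward zero expression
  expect_lt(mean(stage2[, "A"]), 0.05)
})
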