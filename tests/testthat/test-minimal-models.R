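test_that("conditional auto-activation reduces to plain activation as K3 -> Inf", {
  base <- minimal_model_spec("act_1site", K1 = 300, p = 0.5, omega = 50)
  cond <- minimal_model_spec("cond_auto_act", K1 = 300, K3 = 1e15,
                             p = 0.5, omega = 50)
  c1 <- c(0, 10, 100, 500, 1000)
  expect_equal(as.numeric(minimal_response(cond, c1)),
               as.numeric(minimal_response(base, c1)), tolerance = 1e-6)
})

test_that("the unrepressed basal fixed point is c_max p/(1+p)", {
  spec <- minimal_model_spec("rep_2site_coop", K1 = 100, p = 2)
  expect_equal(as.numeric(minimal_response(spec, 0)), 1000 * 2 / 3,
               tolerance = 1e-9)
})

test_that("every minimal layout agrees with the full engine on random parameters", {
  set.seed(2024)
  for (layout in c("act_1site", "act_2site_coop", "cond_auto_act",
                   "rep_2site_coop", "rep_2site_coop_plus_autoact",
                   "lin_rep_unequal_sites")) {
    for (r in 1:8) {
      spec <- minimal_model_spec(layout,
        K1 = 10^stats::runif(1, 0.5, 4), K1b = 10^stats::runif(1, 0.5, 4),
        K3 = 10^stats::runif(1, 1, 4), p = 10^stats::runif(1, -1.5, 1.5),
        omega = stats::runif(1, 1, 100))
      eng <- minimal_to_engine(spec)
      for (c1 in c(0, 30, 500, 1000)) {
        a <- as.numeric(minimal_response(spec, c1))
        b <- steady_state(eng$x, eng$models, c1, 0, 0)
        expect_equal(b, a, tolerance = 1e-4,
                     info = paste(layout, "c1 =", c1))
      }
    }
  }
})

test_that("responses are monotone in the input", {
  up <- minimal_model_spec("cond_auto_act", K1 = 500, K3 = 100, p = 0.3)
  dn <- minimal_model_spec("lin_rep_unequal_sites", K1 = 100, K3 = 150,
                           p = 1)
  c1 <- seq(1, 1000, length.out = 30)
  expect_true(all(diff(as.numeric(minimal_response(up, c1))) >= -1e-9))
  expect_true(all(diff(as.numeric(minimal_response(dn, c1))) <= 1e-9))
})

test_that("sensitivity recovers the analytic gain of known responses", {
  # Hill coefficient 2: S approaches 2 from below as c1 -> 0
  hill2 <- function(c1) 1000 * c1^2 / (200^2 + c1^2)
  expect_equal(sensitivity(hill2, 1e-3), 2, tolerance = 1e-6)
  expect_lt(max(sensitivity(hill2, c(1, 10, 100, 1000))), 2)
  # linear response: S = 1 everywhere; constant response: S = 0
  expect_equal(sensitivity(function(c1) 42 * c1, c(3, 77, 500)),
               rep(1, 3), tolerance = 1e-9)
  expect_equal(sensitivity(function(c1) rep(5, length(c1)), 10), 0)
  expect_error(sensitivity(function(c1) 0 * c1, 5), "zero response")
})

test_that("two cooperative repressor sites cannot exceed sensitivity 2", {
  res <- max_sensitivity(
    minimal_model_spec("rep_2site_coop"),
    c1_range = c(1, 10000),
    param_ranges = list(K1 = c(1, 10000), omega = c(1, 100),
                        p = c(0.1, 100)),
    per_decade = 6, n_c1 = 201)
  expect_lte(res$s_max, 2 + 1e-3)
  expect_gt(res$s_max, 1.9) # the sweep approaches the bound
})

test_that("auto-activation lets repression exceed the two-site bound", {
  spec <- minimal_model_spec("rep_2site_coop_plus_autoact",
                             K1 = 10, K3 = 10, p = 1, omega = 100)
  s <- sensitivity(spec, exp(seq(log(10), log(3000), length.out = 80)))
  expect_gt(max(s), 2)
})

test_that("conditional auto-activation sensitivity grows as recruitment weakens", {
  s_max <- vapply(c(1, 0.1, 0.01, 1e-3), function(p) {
    spec <- minimal_model_spec("cond_auto_act", K1 = 1000, K3 = 50,
                               p = p, omega = 50)
    max(sensitivity(spec, exp(seq(log(1), log(10000), length.out = 120))))
  }, 0)
  expect_true(all(diff(s_max) > 0)) # monotone over three decades of p
})

test_that("affinity optimization improves the fit and respects its contract", {
  gate <- gate_spec("ACT")
  o1 <- optimize_affinities(minimal_model_spec("act_1site", p = 0.5),
                            gate, n_restarts = 6, seed = 1)
  o2 <- optimize_affinities(minimal_model_spec("act_2site_coop", p = 0.5),
                            gate, n_restarts = 6, seed = 1)
  # cooperative activation fits the step goal better than a single site
  expect_lt(o2$e_rf, o1$e_rf)
  # optimization never returns something worse than its best start
  expect_lte(o1$e_rf, min(o1$starts))

  # re-optimizing from an optimum does not regress
  o1b <- optimize_affinities(o1$spec, gate, n_restarts = 1, seed = 2)
  expect_lte(o1b$e_rf, o1$e_rf + 1e-6)
})

test_that("optimizing a linear-activation goal abolishes the auto-regulatory site", {
  gate <- gate_spec("LACT")
  # with a reasonable basal promoter the TF3 operator is driven to the
  # weak-binding bound (effective removal) and feedback buys nothing over
  # plain single-site activation
  o <- optimize_affinities(minimal_model_spec("cond_auto_act", p = 5),
                           gate, n_restarts = 8, seed = 3)
  expect_gt(o$spec$K3, 1e5)
  o0 <- optimize_affinities(minimal_model_spec("act_1site", p = 5),
                            gate, n_restarts = 8, seed = 3)
  expect_lt(abs(o$e_rf - o0$e_rf) / o0$e_rf, 0.01)
  # replacement principle: swapping the TF3 operator for a TF1 site (same
  # layout, no feedback) never fits a linear-activation goal worse
  for (p in c(0.5, 5)) {
    oc <- optimize_affinities(minimal_model_spec("cond_auto_act", p = p),
                              gate, n_restarts = 8, seed = 3)
    ot <- optimize_affinities(minimal_model_spec("act_2site_coop", p = p),
                              gate, n_restarts = 8, seed = 3)
    expect_lte(ot$e_rf, oc$e_rf * 1.001)
  }
})

test_that("linear repression with auto-activation fits the LIN goal better", {
  gate <- gate_spec("LIN")
  on <- optimize_affinities(
    minimal_model_spec("lin_rep_unequal_sites", p = 5, omega = 50),
    gate, n_restarts = 8, seed = 5)
  off <- optimize_affinities(
    minimal_model_spec("rep_2site_coop", p = 5, omega = 50),
    gate, n_restarts = 8, seed = 5)
  expect_lt(on$e_rf, off$e_rf)
})

test_that("the total-derivative identity holds along the fixed-point branch", {
  spec <- minimal_model_spec("lin_rep_unequal_sites", K1 = 60, K1b = 1800,
                             K3 = 150, p = 5, omega = 50)
  chk <- linear_repression_derivative_check(spec, c1_range = c(1, 1000))
  expect_lt(chk$max_resid, 1e-6)

  # without auto-regulation the denominator is exactly 1
  spec0 <- minimal_model_spec("rep_2site_coop", K1 = 60, K1b = 1800, p = 5)
  chk0 <- linear_repression_derivative_check(spec0, c1_range = c(1, 1000))
  expect_equal(chk0$details$denominator, rep(1, nrow(chk0$details)),
               tolerance = 1e-9)
  expect_lt(chk0$max_resid, 1e-6)

  # constant-response degenerate case: both sides vanish
  flat <- minimal_model_spec("rep_2site_coop", K1 = 1e12, K1b = 1e12, p = 1)
  chkf <- linear_repression_derivative_check(flat, c1_range = c(1, 1000))
  expect_lt(max(abs(chkf$details$lhs)), 1e-9)
  expect_lt(chkf$max_resid, 1e-9)
})
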