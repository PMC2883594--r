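test_that("constitutive steady state is the linear ODE fixed point", {
  # P_on constant p: c3* = c_max * p
  for (q in c(0.05, 1, 4)) {
    sm <- constitutive_model(q)
    p <- q / (1 + q)
    expect_equal(steady_state(sm, default_models, 0, 0, 0), 1000 * p,
                 tolerance = 1e-6)
  }
})

test_that("a silent gene settles at zero", {
  sm <- constitutive_model(1e-12)
  expect_equal(steady_state(sm, default_models, 0, 0, 500), 0,
               tolerance = 1e-3)
})

test_that("auto-activating steady state matches a bisection oracle", {
  # a recruiting TF3 site creates feedback; compare against an independent
  # bisection on g(c) = beta*P_on(c) - mu*c
  L <- 80L
  fp <- cisevolve:::footprint_coords(L)
  sm <- site_model(L, data.frame(tf = "TF3", start = fp$lo - 11L, kd = 800),
                   q_R = 0.05)
  em <- engine_model_of(sm, default_models)
  g <- function(c) 1000 * cisevolve:::.pon_cpp(em, c(0, 0, c)) - c
  lo <- 0; hi <- 1000
  stopifnot(g(lo) > 0, g(hi) < 0)
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  oracle <- (lo + hi) / 2
  expect_equal(steady_state(sm, default_models, 0, 0, 0), oracle,
               tolerance = 1e-6)
})

test_that("bistability detection and the dense scan agree", {
  # constitutive gene: single state, no penalty
  sm <- constitutive_model(0.5)
  db <- detect_bistability(sm, default_models, 0, 0)
  expect_equal(db$ss_low, db$ss_high, tolerance = 1e-6)
  expect_equal(db$penalty, 0)
  expect_length(bistability_scan(sm, default_models, 0, 0), 1)

  # strong cooperative auto-activation on a weak promoter: two states
  bis <- reference_design("bistable_autoact", default_models, seed = 1)
  db2 <- detect_bistability(bis, default_models, 0, 0)
  expect_gt(db2$ss_high - db2$ss_low, default_models$dyn$eps_ss)
  expect_gt(db2$penalty, 0)
  roots <- bistability_scan(bis, default_models, 0, 0)
  expect_gte(length(roots), 2)
  # the scan contains both detect_bistability limits
  expect_true(any(abs(roots - db2$ss_low) < 1e-3))
  expect_true(any(abs(roots - db2$ss_high) < 1e-3))

  # monostable auto-repressor: no penalty
  L <- 80L
  fp <- cisevolve:::footprint_coords(L)
  ar <- site_model(L, data.frame(tf = "TF3", start = fp$lo + 5L, kd = 100),
                   q_R = 1)
  expect_equal(detect_bistability(ar, default_models, 0, 0)$penalty, 0)

  # P_on ~ 0: single root at zero
  expect_equal(bistability_scan(constitutive_model(1e-12),
                                default_models, 0, 0), 0, tolerance = 1e-6)
})

test_that("steady states satisfy the residual contract", {
  set.seed(5)
  for (r in 1:10) {
    toy <- random_toy(L = 60)
    dyn <- toy$models$dyn
    ss <- steady_state(toy$x, toy$models, toy$conc[1], toy$conc[2], 0)
    resid <- dyn$beta * promoter_occupancy(toy$x, toy$models, toy$conc[1],
                                           toy$conc[2], ss) - dyn$mu * ss
    expect_lt(abs(resid), dyn$mu * dyn$eps_ss)
  }
})

test_that("response time matches the exponential-relaxation closed form", {
  sm <- constitutive_model(0.25) # c3* = 200
  ss <- 1000 * 0.25 / 1.25
  for (init in c(0, 1000)) {
    expected <- log(abs(init - ss) / default_models$dyn$eps_rt)
    expect_equal(response_time(sm, default_models, 0, 0, init), expected,
                 tolerance = 1e-3)
  }
  # starting at the steady state: zero
  expect_equal(response_time(sm, default_models, 0, 0, ss), 0)
})

test_that("response time agrees with an independent ODE solver", {
  skip_if_not_installed("deSolve")
  L <- 80L
  fp <- cisevolve:::footprint_coords(L)
  sm <- site_model(L, data.frame(tf = "TF3", start = fp$lo + 5L, kd = 150),
                   q_R = 1) # auto-repressor
  em <- engine_model_of(sm, default_models)
  ode <- deSolve::ode(
    y = c(c = 0), times = seq(0, 20, by = 0.0005), parms = NULL,
    func = function(t, y, parms)
      list(1000 * cisevolve:::.pon_cpp(em, c(0, 0, max(y, 0))) - y),
    method = "ode45")
  ss <- steady_state(sm, default_models, 0, 0, 0)
  t_oracle <- unname(ode[which(abs(ode[, "c"] - ss) < 1)[1], "time"])
  expect_equal(response_time(sm, default_models, 0, 0, 0), t_oracle,
               tolerance = 2e-3)
})

test_that("auto-repression speeds up the response relative to a matched constitutive gene", {
  L <- 80L
  fp <- cisevolve:::footprint_coords(L)
  ar <- site_model(L, data.frame(tf = "TF3", start = fp$lo + 5L, kd = 150),
                   q_R = 1)
  ss <- steady_state(ar, default_models, 0, 0, 0)
  # constitutive gene with the same steady state
  p <- ss / 1000
  cm <- constitutive_model(p / (1 - p))
  expect_equal(steady_state(cm, default_models, 0, 0, 0), ss,
               tolerance = 1e-3)
  expect_lt(response_time(ar, default_models, 0, 0, 0),
            response_time(cm, default_models, 0, 0, 0))
})

test_that("intrinsic noise has the Poisson limit and the feedback asymmetry", {
  # constitutive: sigma = sqrt(c3*/V) exactly (f' = 0)
  for (q in c(0.1, 1)) {
    sm <- constitutive_model(q)
    ss <- steady_state(sm, default_models, 0, 0, 0)
    expect_equal(as.numeric(intrinsic_noise_sd(sm, default_models, 0, 0)),
                 sqrt(ss), tolerance = 1e-3)
  }
  L <- 80L
  fp <- cisevolve:::footprint_coords(L)
  # auto-activation (f' > 0) amplifies noise relative to matched constitutive
  aa <- site_model(L, data.frame(tf = "TF3", start = fp$lo - 11L, kd = 3000),
                   q_R = 0.05)
  ss_aa <- steady_state(aa, default_models, 0, 0, 0)
  cm_aa <- constitutive_model(ss_aa / (1000 - ss_aa))
  expect_gt(as.numeric(intrinsic_noise_sd(aa, default_models, 0, 0)),
            as.numeric(intrinsic_noise_sd(cm_aa, default_models, 0, 0)))
  # auto-repression (f' < 0) reduces it
  ar <- site_model(L, data.frame(tf = "TF3", start = fp$lo + 5L, kd = 150),
                   q_R = 1)
  ss_ar <- steady_state(ar, default_models, 0, 0, 0)
  cm_ar <- constitutive_model(ss_ar / (1000 - ss_ar))
  expect_lt(as.numeric(intrinsic_noise_sd(ar, default_models, 0, 0)),
            as.numeric(intrinsic_noise_sd(cm_ar, default_models, 0, 0)))
})

test_that("noise diverges as the restoring force vanishes", {
  # increasingly strong auto-activation at the fixed point drives f' -> mu
  L <- 80L
  fp <- cisevolve:::footprint_coords(L)
  sds <- f1s <- numeric(0)
  for (kd in c(20000, 10000, 6000)) {
    aa <- site_model(L, data.frame(tf = "TF3", start = fp$lo - 11L, kd = kd),
                     q_R = 0.02)
    s <- intrinsic_noise_sd(aa, default_models, 0, 0)
    sds <- c(sds, as.numeric(s))
    f1s <- c(f1s, attr(s, "f1"))
  }
  expect_true(all(diff(f1s) > 0)) # f' increases toward mu
  expect_true(all(diff(sds) > 0)) # sigma increases monotonically
})

test_that("response_surface evaluates every grid point deterministically", {
  sm <- constitutive_model(0.5)
  grid <- evaluation_grid(2L)
  surf <- response_surface(sm, default_models, grid)
  expect_equal(nrow(surf), 16)
  expect_equal(stats::sd(surf$c3), 0) # constant surface
  g <- reference_design("AND_heterocoop", default_models, seed = 1)
  corners <- evaluation_grid(2L, "corners")
  s1 <- response_surface(g, default_models, corners)
  s2 <- response_surface(g, default_models, corners)
  expect_identical(s1, s2)
  # AND fixture: high only in the high/high corner
  expect_gt(s1$c3[4], 500)
  expect_true(all(s1$c3[1:3] < 500))
  expect_error(response_surface(sm, default_models, grid[0, ]), "empty")
})
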