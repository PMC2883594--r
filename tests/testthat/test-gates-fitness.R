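test_that("goal functions reproduce the gate truth tables", {
  lohi <- c(125, 875)
  truth <- list( # rows: (lo,lo), (lo,hi), (hi,lo), (hi,hi)
    AND  = c(0, 0, 0, 1000),
    OR   = c(0, 1000, 1000, 1000),
    NOR  = c(1000, 0, 0, 0),
    NAND = c(1000, 1000, 1000, 0))
  for (nm in names(truth)) {
    gate <- gate_spec(nm)
    k <- 1
    for (c1 in lohi) for (c2 in lohi) {
      # note truth rows are ordered (c1 class, c2 class)
      expect_equal(goal_function(gate, c1, c2),
                   truth[[nm]][2 * (c1 == 875) + (c2 == 875) + 1],
                   info = paste(nm, c1, c2))
      k <- k + 1
    }
  }
  expect_equal(goal_function(gate_spec("ACT"), 875), 1000)
  expect_equal(goal_function(gate_spec("ACT"), 125), 0)
  expect_equal(goal_function(gate_spec("IN"), 875), 0)
  expect_equal(goal_function(gate_spec("IN"), 125), 1000)
  # linear gates
  expect_equal(goal_function(gate_spec("LACT"), 250), 250)
  expect_equal(goal_function(gate_spec("LIN"), 0), 1000)
  expect_equal(goal_function(gate_spec("LIN"), 1000), 0)
  expect_equal(goal_function(gate_spec("MEAN"), 125, 875), 500)
  expect_equal(goal_function(gate_spec("NMEAN"), 125, 875), 500)
  expect_equal(goal_function(gate_spec("NMEAN"), 1000, 1000), 0)
  expect_error(goal_function(gate_spec("AND"), -5, 100), "lie in")
  expect_error(goal_function(gate_spec("LACT"), 1500), "lie in")
})

test_that("evaluation grids have the documented shape", {
  g2 <- evaluation_grid(gate_spec("NAND"))
  expect_equal(nrow(g2), 16)
  expect_setequal(unique(g2$c1), c(125, 375, 625, 875))
  g1 <- evaluation_grid(gate_spec("LACT"))
  expect_equal(nrow(g1), 7)
  expect_equal(g1$c1, seq(0, 1000, length.out = 7))
  expect_equal(nrow(evaluation_grid(2L, type = "corners")), 4)
})

test_that("E_RF is the goal-normalized sum of squares plus the bistability penalty", {
  gate <- gate_spec("AND")
  grid <- evaluation_grid(gate)
  goals <- goal_function(gate, grid$c1, grid$c2)
  # surface == goal: E_RF = 0
  perfect <- structure(data.frame(c1 = grid$c1, c2 = grid$c2, c3 = goals,
                                  ss_high = goals, penalty = 0),
                       class = c("response_surface", "data.frame"))
  expect_equal(fitness_rf(perfect, gate), 0)
  # uniform 100 nM deviation at 16 points, c0 = 1: 16 * 1e4
  off <- perfect
  off$c3 <- goals + 100
  expect_equal(fitness_rf(off, gate), 160000)
  # random surface: direct summation oracle
  set.seed(12)
  rnd <- perfect
  rnd$c3 <- stats::runif(16, 0, 1000)
  rnd$penalty <- stats::runif(16, 0, 10)
  oracle <- sum((rnd$c3 - goals)^2) + sum(rnd$penalty)
  expect_equal(fitness_rf(rnd, gate), oracle, tolerance = 1e-9)
})

test_that("E_RT sums the 32 closed-form relaxation times of a constitutive gate", {
  sm <- constitutive_model(0.25)
  ss <- 200
  grid <- evaluation_grid(2L)
  expected <- 16 * (log((1000 - ss) / 1) + log(ss / 1))
  expect_equal(fitness_rt(sm, default_models, grid), expected,
               tolerance = 1e-3)
})

test_that("E_N of a constitutive gate is 16 * sqrt(c3*/V); zero expression gives 0", {
  sm <- constitutive_model(0.25)
  grid <- evaluation_grid(2L)
  expect_equal(fitness_noise(sm, default_models, grid), 16 * sqrt(200),
               tolerance = 1e-3)
  silent <- constitutive_model(1e-12)
  expect_lt(fitness_noise(silent, default_models, grid), 1e-3)
})

test_that("the auto-repressor fixture beats its matched constitutive gene on both dynamic measures", {
  L <- 80L
  fp <- cisevolve:::footprint_coords(L)
  ar <- site_model(L, data.frame(tf = "TF3", start = fp$lo + 5L, kd = 150),
                   q_R = 1)
  ss <- steady_state(ar, default_models, 0, 0, 0)
  cm <- constitutive_model(ss / (1000 - ss))
  grid <- evaluation_grid(2L)
  expect_lt(fitness_rt(ar, default_models, grid),
            fitness_rt(cm, default_models, grid))
  expect_lt(fitness_noise(ar, default_models, grid),
            fitness_noise(cm, default_models, grid))
})

test_that("the lambda ramp rises linearly from zero and saturates", {
  expect_equal(lambda_ramp(0, 5, 100), 0)
  expect_equal(lambda_ramp(50, 5, 100), 2.5)
  expect_equal(lambda_ramp(100, 5, 100), 5)
  expect_equal(lambda_ramp(5000, 5, 100), 5)
  expect_true(!is.unsorted(lambda_ramp(0:200, 5, 100)))
})

test_that("the composite score combines the components and stays positive", {
  w <- fitness_weights(S0 = 1e7)
  expect_equal(fitness_total(0, 0, 0, w), 1e7) # perfect gate
  expect_equal(fitness_total(160000, 0, 0, w), 9840000)
  # ranking invariance: adding a constant to S0 preserves order
  w2 <- fitness_weights(S0 = 2e7)
  e <- c(100, 5000, 3.2e6)
  s1 <- vapply(e, function(x) fitness_total(x, 0, 0, w), 0)
  s2 <- vapply(e, function(x) fitness_total(x, 0, 0, w2), 0)
  expect_equal(order(s1), order(s2))
  expect_error(fitness_total(2e7, 0, 0, w), "S0")
  expect_error(fitness_total(-1, 0, 0, w))
})
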