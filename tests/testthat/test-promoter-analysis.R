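test_that("the feedback measure obeys its defining arithmetic", {
  # uniform 100 nM shift at every point: F = 1e4 nM^2 by definition
  n <- rep(c(200, 700), 8)
  expect_equal(feedback_from_surfaces(n + 100, n), 1e4)
  expect_equal(feedback_from_surfaces(n, n), 0)
  expect_error(feedback_from_surfaces(n, n[-1]))
})

test_that("F is zero without TF3 affinity and large for the auto-activator fixture", {
  # explicit model with no TF3 sites at all
  L <- 80L
  fp <- cisevolve:::footprint_coords(L)
  sm <- site_model(L, data.frame(tf = "TF1", start = fp$lo - 11L, kd = 500),
                   q_R = 0.2)
  expect_equal(feedback_measure(sm, default_models), 0)

  # constructed auto-activator: F matches a direct two-surface computation
  aa <- site_model(L, data.frame(tf = c("TF1", "TF3"),
                                 start = c(fp$lo - 11L, fp$lo - 20L - 9L + 3L),
                                 kd = c(500, 300)), q_R = 0.2)
  grid <- evaluation_grid(2L)
  f <- feedback_measure(aa, default_models, grid)
  s_full <- response_surface(aa, default_models, grid)
  aa0 <- site_model(L, data.frame(tf = "TF1", start = fp$lo - 11L, kd = 500),
                    q_R = 0.2)
  s_null <- response_surface(aa0, default_models, grid)
  expect_equal(f, mean((s_full$c3 - s_null$c3)^2), tolerance = 1e-9)
  expect_gt(f, 1e3)
})

test_that("F is invariant under relabelling TF1 and TF2 in a symmetric layout", {
  L <- 80L
  fp <- cisevolve:::footprint_coords(L)
  mk <- function(tfa, tfb) site_model(
    L, data.frame(tf = c(tfa, tfb, "TF3"),
                  start = c(fp$lo - 11L, fp$lo - 32L, 2L),
                  kd = c(800, 800, 400)), q_R = 0.1)
  f12 <- feedback_measure(mk("TF1", "TF2"), default_models)
  f21 <- feedback_measure(mk("TF2", "TF1"), default_models)
  expect_equal(f12, f21, tolerance = 1e-9)
})

test_that("footprints report the maximal corner occupancy of every site", {
  L <- 80L
  fp <- cisevolve:::footprint_coords(L)
  sm <- site_model(L, data.frame(tf = c("TF1", "TF2"),
                                 start = c(0L, 20L), kd = c(5, 1e9)),
                   q_R = 0.3)
  prof <- footprint(sm, default_models)
  # TF2 is essentially non-binding; TF1 site saturates at c1 = 1000
  expect_gte(prof$o_max[prof$tf == "TF1" & prof$start == 0], 0.99)
  expect_true(all(prof$o_max[prof$tf == "TF2"] < 1e-3))
  expect_true(all(prof$o_max >= 0 & prof$o_max <= 1))

  # zero-concentration TF: occupancy 0 at every corner (TF3 with silent gene)
  expect_true(all(prof$o_max[prof$tf == "TF3"] == 0))

  # against a per-corner enumeration oracle on a small system
  toy <- site_model(40L, data.frame(tf = c("TF1", "TF3"),
                                    start = c(0L, 12L), kd = c(300, 700)),
                    q_R = 0.5, l_tf = 9L)
  prof2 <- footprint(toy, default_models)
  em <- engine_model_of(toy, default_models)
  dyn <- default_models$dyn
  for (i in 1:4) {
    corners <- evaluation_grid(2L, "corners")
    ss <- cisevolve:::.steady_state_cpp(em, corners$c1[i], corners$c2[i], 0,
                                        dyn$beta, dyn$mu, dyn$eps_ss)
    oracle <- enum_partition(em, c(corners$c1[i], corners$c2[i], ss))
    expect_lte(oracle$occ[[1]][1], # TF1 at start 0 in this corner
               prof2$o_max[prof2$tf == "TF1" & prof2$start == 0] + 1e-9)
  }
})

test_that("binding-site calls threshold, merge overlaps and annotate roles", {
  L <- 80L
  fp <- cisevolve:::footprint_coords(L)
  sm <- site_model(L, data.frame(tf = c("TF1", "TF2", "TF3"),
                                 start = c(fp$lo - 11L, fp$lo + 5L, 0L),
                                 kd = c(20, 30, 25)), q_R = 0.3)
  prof <- footprint(sm, default_models)
  calls <- call_binding_sites(prof, default_models)
  expect_setequal(calls$role[calls$tf == "TF1"], "activator")
  expect_setequal(calls$role[calls$tf == "TF2"], "repressor")
  expect_setequal(calls$role[calls$tf == "TF3"], "auto-distal")
  expect_equal(calls$end - calls$start, rep(9L, nrow(calls)))

  # impossible threshold: empty, and monotone non-increasing in threshold
  expect_equal(nrow(call_binding_sites(prof, default_models, 1.01)), 0)
  n_calls <- vapply(c(0.1, 0.3, 0.5, 0.9), function(th)
    nrow(call_binding_sites(prof, default_models, th)), 0L)
  expect_true(all(diff(n_calls) <= 0))

  # empty profile: empty call set
  empty <- footprint(constitutive_model(0.5), default_models)
  expect_equal(nrow(call_binding_sites(empty, default_models)), 0)
})

test_that("simplified models reproduce the full response within tolerance", {
  g <- reference_design("NAND_autoact", default_models, seed = 2)
  prof <- footprint(g, default_models)
  grid <- evaluation_grid(2L)
  # the stringent 0.5 cutoff usually suffices; when it does not, lowering
  # the threshold recovers the weak-but-important sites
  sv <- NULL
  for (th in c(0.5, 0.25, 0.1)) {
    calls <- call_binding_sites(prof, default_models, th)
    if (nrow(calls) < 3) next
    sv <- simplify_and_verify(g, calls, default_models, grid)
    if (sv$success) break
  }
  expect_gte(nrow(calls), 3)
  expect_true(sv$success)
  expect_lte(sv$max_dev, 50)

  # ablating the strongest called site breaks the reduction
  drop <- which.max(calls$o_max)
  sv2 <- simplify_and_verify(g, calls[-drop, ], default_models, grid)
  expect_gt(sv2$max_dev, 50)
  expect_error(simplify_and_verify(g, calls[0, ], default_models, grid),
               "no called sites")
})

test_that("degree statistics reproduce per-class counts and means", {
  rec <- data.frame(
    class = c(rep("auto-activator", 3), rep("auto-repressor", 2)),
    n_inputs = c(0, 2, 4, 0, 1))
  st <- degree_stats(rec)
  aa <- st[st$class == "auto-activator", ]
  expect_equal(aa$n, 3)
  expect_equal(aa$total_inputs, 6)
  expect_equal(aa$mean_in_degree, 2)
  expect_equal(aa$frac_with_input, 2 / 3)
  # single TF with no inputs
  one <- degree_stats(data.frame(class = "auto-repressor", n_inputs = 0))
  expect_equal(one$frac_with_input, 0)
  expect_equal(one$mean_in_degree, 0)
  expect_error(degree_stats(data.frame()), "record")
})
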