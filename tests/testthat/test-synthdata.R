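test_that("parameter sets validate their invariants", {
  p <- default_sim_params("control_like")
  expect_s3_class(p, "sim_params")
  expect_equal(rowSums(p$transition), rep(1, 3), ignore_attr = TRUE)
  expect_equal(rowSums(p$morph_emission), rep(1, 3), ignore_attr = TRUE)
  expect_true(all(p$dir_kappa >= 0))
  expect_lt(p$speed_median[["rest"]], 10)

  m <- default_sim_params("mutant_like")
  # encoded orderings of the two conditions
  expect_lt(m$dir_kappa[["slow"]], p$dir_kappa[["slow"]])
  expect_equal(m$dir_kappa[["spurt"]], p$dir_kappa[["spurt"]])
  expect_gt(m$fraction_never_migrating, p$fraction_never_migrating)
  expect_lt(m$transition["rest", "spurt"], p$transition["rest", "spurt"])
  expect_equal(m$dt, p$dt)
  expect_equal(m$n_frames, p$n_frames)
  expect_equal(p$n_frames, 27L)
  expect_equal(p$dt, 1 / 6)

  expect_error(sim_params(transition = matrix(1, 3, 3),
                          speed_median = p$speed_median,
                          speed_sdlog = p$speed_sdlog,
                          dir_mean_deg = p$dir_mean_deg,
                          dir_kappa = p$dir_kappa,
                          fraction_never_migrating = 0.1,
                          morph_emission = p$morph_emission,
                          branch_event_rate = 0.1),
               "sum to 1")
  expect_error(do.call(sim_params, utils::modifyList(
    list(transition = p$transition, speed_median = p$speed_median,
         speed_sdlog = p$speed_sdlog, dir_mean_deg = p$dir_mean_deg,
         dir_kappa = p$dir_kappa, fraction_never_migrating = 0.1,
         morph_emission = p$morph_emission, branch_event_rate = 0.1),
    list(dir_kappa = c(-1, 0, 2)))), "kappa")
})

test_that("set_spurt_entry rewrites rows and keeps them stochastic", {
  p <- default_sim_params("control_like")
  p2 <- set_spurt_entry(p, 0.15)
  expect_equal(p2$transition["rest", "spurt"], 0.15)
  expect_equal(p2$transition["slow", "spurt"], 0.15)
  expect_equal(rowSums(p2$transition), rep(1, 3), ignore_attr = TRUE)
  expect_equal(p2$transition["spurt", ], p$transition["spurt", ])
})

test_that("simulation is deterministic under a fixed seed", {
  p <- default_sim_params("control_like")
  s1 <- simulate_population(p, 40, seed = 123)
  s2 <- simulate_population(p, 40, seed = 123)
  expect_identical(s1$population$tracks, s2$population$tracks)
  expect_identical(s1$morphology, s2$morphology)
  expect_identical(s1$truth$states, s2$truth$states)
  s3 <- simulate_population(p, 40, seed = 124)
  expect_false(identical(s1$population$tracks, s3$population$tracks))
})

test_that("a fully rest-locked population is classified non-migratory", {
  p <- default_sim_params("control_like")
  p$fraction_never_migrating <- 1
  sim <- simulate_population(p, 60, seed = 9)
  cls <- analyze_population(sim$population)$features$speed_class
  expect_true(all(cls == "non_migratory"))
})

test_that("high-concentration spurt-only chains concentrate trajectories", {
  p <- default_sim_params("control_like")
  p$transition <- matrix(c(0, 0, 1, 0, 0, 1, 0, 0, 1), 3, 3, byrow = TRUE,
                         dimnames = dimnames(p$transition))
  p$dir_kappa[["spurt"]] <- 50
  p$fraction_never_migrating <- 0
  sim <- simulate_population(p, 500, seed = 31)
  feats <- analyze_population(sim$population)$features
  ang <- feats$trajectory_angle_deg
  s <- circular_summary(ang[!is.na(ang)])
  expect_lt(abs(s$mean_deg - 90), 3)
  expect_gt(s$resultant_R, 0.9)
})

test_that("isotropic parameters yield a uniform pooled angle distribution", {
  p <- default_sim_params("control_like")
  p$dir_kappa[] <- 0
  sim <- simulate_population(p, 2000, seed = 77)
  feats <- analyze_population(sim$population)$features
  ang <- feats$trajectory_angle_deg
  lf <- lateral_fraction(ang[!is.na(ang)])
  expect_lt(abs(lf - 0.25), 0.03)
})

test_that("parameter recovery reproduces the configured ground truth", {
  p <- default_sim_params("control_like")
  sim <- simulate_population(p, 500, seed = 55)
  rec <- recover_parameters(sim)
  expect_lt(rec$rest_occupancy_error, 0.03)
  expect_lt(rec$spurt_mean_error, 5)
  # kappa proxy ordering follows the configured concentrations
  r <- rec$step_resultant_by_state
  expect_gt(r[["spurt"]], r[["slow"]])
  expect_gt(r[["slow"]], r[["rest"]])
  # truth must match the population it came from
  sim2 <- simulate_population(p, 10, seed = 56)
  bad <- sim
  bad$truth <- sim2$truth
  expect_error(recover_parameters(bad), "does not match")
})

test_that("morphology output respects its invariants", {
  sim <- simulate_population(default_sim_params("mutant_like"), 50, seed = 8)
  m <- sim$morphology
  expect_true(all(m$n_branches_total >= 0))
  expect_equal(nrow(m), 50 * 27)
  expect_true(all(m$n_soma_processes >= 2))
})

test_that("parameter files round-trip through the flat key/value format", {
  p <- default_sim_params("mutant_like")
  path <- withr::local_tempfile(fileext = ".cfg")
  write_sim_params(p, path)
  q <- read_sim_params(path)
  expect_equal(q$transition, p$transition)
  expect_equal(q$speed_median, p$speed_median)
  expect_equal(q$dir_kappa, p$dir_kappa)
  expect_equal(q$dt, p$dt)
  expect_equal(q$condition, p$condition)
  expect_equal(q$bipolar_speed_min, p$bipolar_speed_min)
})
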