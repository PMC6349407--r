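test_that("trajectory angles follow the midline-referenced convention", {
  # purely lateral displacement -> 90 degrees
  expect_equal(trajectory_angle(rbind(c(0, 0, 0), c(5, 0, 0)), "right"), 90)
  # along the midline (+y) -> 0 degrees
  expect_equal(trajectory_angle(rbind(c(0, 0, 0), c(0, 7, 3)), "right"), 0)
  # medial-and-forward on the right side
  expect_equal(trajectory_angle(rbind(c(0, 0, 0), c(-3, 3, 0)), "right"), -45)
  # left-side cells are mirrored so that lateral is +x for everyone
  expect_equal(trajectory_angle(rbind(c(0, 0, 0), c(-5, 0, 0)), "left"), 90)
  # zero xy-displacement (z-only motion) is undefined
  expect_warning(
    a <- trajectory_angle(rbind(c(0, 0, 0), c(0, 0, 4)), "right"),
    "undefined")
  expect_true(is.na(a))
})

test_that("lateral fraction uses the closed 45-135 degree band", {
  expect_equal(lateral_fraction(c(90, 0, 100, -60)), 0.5)
  expect_equal(lateral_fraction(c(45, 135)), 1)
  expect_equal(lateral_fraction(rep(-90, 5)), 0)
  expect_error(lateral_fraction(numeric(0)), "non-empty")
})

test_that("circular summaries match hand-derived values", {
  s1 <- circular_summary(c(90, 90, 90))
  expect_equal(s1$mean_deg, 90)
  expect_equal(s1$resultant_R, 1)
  expect_equal(s1$ang_dev_deg, 0)

  # {0, 90}: C = S = 0.5, R = sqrt(0.5), ang dev = sqrt(2(1-R)) rad
  s2 <- circular_summary(c(0, 90))
  expect_equal(s2$mean_deg, 45)
  expect_equal(s2$resultant_R, sqrt(0.5))
  expect_equal(s2$ang_dev_deg, sqrt(2 * (1 - sqrt(0.5))) * 180 / pi,
               tolerance = 1e-10)
  expect_equal(s2$ang_dev_deg, 43.85229, tolerance = 1e-6)

  # antipodal pair: R = 0, mean undefined, deviation at its upper bound
  s3 <- circular_summary(c(0, 180))
  expect_equal(s3$resultant_R, 0, tolerance = 1e-12)
  expect_true(is.na(s3$mean_deg))
  expect_equal(s3$ang_dev_deg, sqrt(2) * 180 / pi, tolerance = 1e-6)
})

test_that("circular summary recovers a von Mises mean direction", {
  set.seed(2024)
  a <- saltatrack:::rvonmises(2000, 37, kappa = 1)
  s <- circular_summary(a)
  expect_lt(abs(s$mean_deg - 37), 5)
  # mean shifts with a common rotation; R and deviation are invariant
  s_rot <- circular_summary(saltatrack:::wrap_angle(a + 100))
  expect_equal(s_rot$resultant_R, s$resultant_R)
  expect_equal(s_rot$ang_dev_deg, s$ang_dev_deg)
  expect_equal(saltatrack:::wrap_angle(s_rot$mean_deg - s$mean_deg), 100,
               tolerance = 1e-6)
})

test_that("Kuiper V matches hand-derivable cases", {
  same <- kuiper_test(c(10, 50, 90), c(10, 50, 90))
  expect_equal(same$V, 0)
  expect_equal(same$p, 1)

  expect_equal(kuiper_test(0, 180)$V, 1)
  expect_equal(kuiper_test(c(0, 90, 180, 270), c(45, 135, 225, 315))$V, 0.25)
})

test_that("Kuiper V equals the all-origins ECDF oracle on random pairs", {
  set.seed(7)
  for (i in 1:50) {
    n1 <- sample(2:12, 1)
    n2 <- sample(2:12, 1)
    a <- runif(n1, -180, 180)
    # a mix of unrelated samples, rotated copies (tie-heavy), and overlaps
    b <- switch(sample(3, 1),
                runif(n2, -180, 180),
                a + sample(c(0, 45, 180), 1),
                c(a, runif(max(n2 - n1, 1), -180, 180)))
    o <- kuiper_oracle(a, b)
    v <- kuiper_test(a, b)$V
    expect_equal(v, o$V, tolerance = 1e-12)
    # origin invariance: every cyclic origin yields the same statistic
    expect_lt(diff(range(o$all_origins)), 1e-12)
  }
})

test_that("Kuiper V is invariant under common rotations past the wrap", {
  set.seed(11)
  a <- runif(30, -180, 180)
  b <- runif(25, -180, 180)
  v0 <- kuiper_test(a, b)$V
  for (shift in c(15, 90, 179, 180, 271, 360.5)) {
    expect_equal(kuiper_test(a + shift, b + shift)$V, v0, tolerance = 1e-12)
  }
  # a linear KS statistic would change under a wrap-crossing rotation
  ks0 <- stats::ks.test(a, b)$statistic
  ar <- saltatrack:::wrap_angle(a + 170)
  br <- saltatrack:::wrap_angle(b + 170)
  ksr <- stats::ks.test(ar, br)$statistic
  expect_false(isTRUE(all.equal(unname(ks0), unname(ksr), tolerance = 1e-9)))
})

test_that("the Kuiper p-value decreases with V and respects bounds", {
  for (nn in list(c(10, 10), c(50, 80), c(500, 600))) {
    ps <- vapply(seq(0.05, 1, by = 0.05),
                 function(v) saltatrack:::kuiper_pvalue(v, nn[1], nn[2]),
                 numeric(1))
    expect_true(all(diff(ps) <= 1e-12))
    expect_true(all(ps >= 0 & ps <= 1))
  }
  # clearly separated samples give a small p
  set.seed(3)
  a <- saltatrack:::rvonmises(100, 0, 4)
  b <- saltatrack:::rvonmises(100, 180, 4)
  expect_lt(kuiper_test(a, b)$p, 1e-6)
})

test_that("polar histograms partition the circle with upper-bin edges", {
  h <- polar_histogram(seq(-179.5, 179.5, by = 1), n_bins = 4)
  expect_equal(sum(h$fraction), 1)
  expect_equal(unname(h$fraction), rep(0.25, 4))

  h2 <- polar_histogram(rep(90, 10), n_bins = 8)
  expect_equal(sum(h2$count > 0), 1)
  expect_equal(h2$fraction[h2$bin_lo == 90], 1)

  # an angle exactly on a bin edge goes to the upper bin
  h3 <- polar_histogram(0, n_bins = 4)
  expect_equal(h3$count[h3$bin_lo == 0], 1)
  expect_error(polar_histogram(numeric(0), 4), "non-empty")
  expect_error(polar_histogram(c(1, 2), 1), "n_bins")
})
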