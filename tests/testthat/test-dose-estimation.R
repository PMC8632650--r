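# Curve inversion and Merkle dose uncertainty.

test_that("curve inversion solves the quadratic on the physical branch", {
  sen <- lq_curve(alpha = 0.168, beta = 0.061)
  expect_equal(invert_curve(sen, 1.648), 4, tolerance = 1e-12)
  expect_equal(invert_curve(sen, 0), 0)
  lin <- lq_curve(alpha = 0.2, beta = 0)
  expect_equal(invert_curve(lin, 0.5), 2.5)
  withbg <- lq_curve(alpha = 0.1, beta = 0.05, C = 0.002)
  expect_equal(invert_curve(withbg, 0.002), 0)
  expect_equal(invert_curve(withbg, 0.001), 0)  # below background
  expect_error(invert_curve(lq_curve(alpha = 0, beta = 0), 1),
               "no dose information")
})

test_that("inversion is the exact inverse of prediction", {
  set.seed(31)
  for (i in 1:20) {
    cv <- lq_curve(alpha = runif(1, 0.01, 0.5), beta = runif(1, 0.01, 0.3),
                   C = runif(1, 0, 0.01))
    D <- runif(10, 0, 10)
    expect_equal(invert_curve(cv, predict(cv, D)), D, tolerance = 1e-9)
  }
})

test_that("dose estimates are ordered lower <= point <= upper", {
  set.seed(63)
  for (i in 1:30) {
    cv <- lq_curve(alpha = runif(1, 0.05, 0.3), beta = runif(1, 0.02, 0.2),
                   C = runif(1, 0, 0.005),
                   se_alpha = runif(1, 0, 0.05),
                   se_beta = runif(1, 0, 0.02))
    est <- estimate_dose(cv, rpois(1, 100), sample(50:500, 1))
    expect_lte(est$lower_gy, est$dose_gy)
    expect_lte(est$dose_gy, est$upper_gy)
    expect_gte(est$lower_gy, 0)
  }
})

test_that("both uncertainty sources collapse to a point when switched off", {
  cv <- lq_curve(alpha = 0.168, beta = 0.061)  # zero-width vcov
  est <- estimate_dose(cv, 165, 100, conf_count = 0)
  expect_equal(est$lower_gy, est$dose_gy, tolerance = 1e-7)
  expect_equal(est$upper_gy, est$dose_gy, tolerance = 1e-7)
})

test_that("a high-dose observation is recovered with bracketing bounds", {
  sen <- lq_curve(alpha = 0.168, beta = 0.061, se_alpha = 0.018,
                  se_beta = 0.006, cov_alpha_beta = -1e-4)
  est <- estimate_dose(sen, 165, 100)
  expect_equal(est$dose_gy, invert_curve(sen, 1.65), tolerance = 1e-9)
  expect_equal(est$dose_gy, 4.0, tolerance = 0.05)
  expect_lt(est$lower_gy, est$dose_gy)
  expect_gt(est$upper_gy, est$dose_gy)
  # interval widens monotonically with the count confidence level
  widths <- vapply(c(0.8, 0.9, 0.95, 0.99), function(cf) {
    e <- estimate_dose(sen, 165, 100, conf_count = cf)
    e$upper_gy - e$lower_gy
  }, 0)
  expect_true(all(diff(widths) > 0))
})

test_that("zero observed count still yields a finite upper bound", {
  sen <- lq_curve(alpha = 0.168, beta = 0.061)
  est <- estimate_dose(sen, 0, 1000)
  expect_equal(est$dose_gy, 0)
  expect_equal(est$lower_gy, 0)
  expect_gt(est$upper_gy, 0)
  # upper bound from the Garwood upper limit of a zero count
  y_up <- exact_poisson_ci(0)$upper / 1000
  expect_equal(est$upper_gy, invert_curve(sen, y_up), tolerance = 1e-6)
  expect_error(estimate_dose(sen, -1, 100), "non-negative")
  expect_error(estimate_dose(sen, 5, 0), ">= 1")
})

test_that("point estimate is monotone in the observed count", {
  sen <- lq_curve(alpha = 0.168, beta = 0.061, se_alpha = 0.018,
                  se_beta = 0.006, cov_alpha_beta = -1e-4)
  pts <- vapply(seq(0, 300, by = 10), function(x)
    estimate_dose(sen, x, 200)$dose_gy, 0)
  expect_true(all(diff(pts) >= 0))
})

test_that("an out-of-bracket upper bound is reported as open", {
  cv <- lq_curve(alpha = 0.05, beta = 0.001, se_alpha = 0.05,
                 se_beta = 0.01)
  est <- estimate_dose(cv, 40, 100, d_max = 10)
  expect_true(est$open_upper)
  expect_equal(est$upper_gy, 10)
  expect_lte(est$dose_gy, 10)
})

test_that("multi-endpoint estimation maps tallies onto matching curves", {
  sp <- cohort_preset("senegal_africa", doses = 2, cells_per_dose = 1000,
                      seed = 17)
  tal <- simulate_tally(sp)
  curves <- lapply(c("dicentrics", "dicentrics_rings", "dsb"),
                   function(ep) reference_curve("senegal_africa", ep))
  ests <- estimate_dose_multi(curves, tal)
  expect_named(ests, c("dicentrics", "dicentrics_rings", "dsb"))
  for (est in ests) {
    expect_lte(est$lower_gy, 2)
    expect_gte(est$upper_gy, 2)
  }
  expect_identical(estimate_dose_multi(list(), tal), list())
  bad <- curves[[1]]
  bad$endpoint <- "nonsense"
  expect_error(estimate_dose_multi(list(bad), tal), "endpoint")
})
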