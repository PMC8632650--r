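# Quasi-Poisson linear-quadratic calibration.

test_that("fit matches an independent brute-force likelihood maximizer", {
  set.seed(101)
  for (i in 1:5) {
    inst <- random_fit_instance()
    fit <- lq_fit_points(inst$D, inst$n, inst$x)
    orc <- oracle_fit_lq(inst$D, inst$n, inst$x)
    ll_fit <- logLik(fit)[1]
    expect_lte(abs(ll_fit - orc$loglik), 1e-4 * abs(orc$loglik))
    expect_lt(max(abs(coef(fit) - orc$theta) /
                    pmax(abs(orc$theta), 1e-2)), 1e-3)
  }
})

test_that("fit agrees with glm quasipoisson identity-link on exposure-weighted counts", {
  # well-interior instance: large exposures, clearly positive C
  set.seed(202)
  D <- c(0.25, 0.5, 1, 2, 4)
  n <- rep(5000, 5)
  x <- rpois(5, n * (0.02 + 0.15 * D + 0.07 * D^2))
  fit <- lq_fit_points(D, n, x, scale_floor = 0)
  gm <- glm(x ~ 0 + I(n) + I(n * D) + I(n * D^2),
            family = quasipoisson(link = "identity"),
            start = pmax(coef(fit), 1e-6))
  expect_equal(unname(coef(fit)), unname(coef(gm)), tolerance = 1e-5)
  if (all(!fit$boundary)) {
    expect_equal(unname(sqrt(diag(vcov(fit)))),
                 unname(summary(gm)$coefficients[, "Std. Error"]),
                 tolerance = 1e-4)
  }
})

test_that("all-zero counts give the flagged degenerate fit", {
  tal <- make_tally(n_cells = 100)
  tal <- do.call(rbind, lapply(c(0, 1, 2), function(D) {
    t <- tal; t$dose_gy <- D; t
  }))
  fit <- lq_fit(tal, endpoint = "dicentrics")
  expect_true(fit$degenerate)
  expect_equal(unname(coef(fit)), c(0, 0, 0))
})

test_that("fewer than 3 distinct doses is an error", {
  tal <- rbind(make_tally(dic = 5, dose_gy = 1),
               make_tally(dic = 9, dose_gy = 2))
  expect_error(lq_fit(tal), "3 distinct doses")
})

test_that("predicted yields follow C + alpha D + beta D^2", {
  sen <- lq_curve(alpha = 0.168, beta = 0.061)
  expect_equal(predict(sen, 4), 1.648)
  expect_equal(predict(sen, 0), 0)
  cau <- lq_curve(alpha = 0.147, beta = 0.128, C = 6 / 5200)
  expect_equal(predict(cau, 1), 6 / 5200 + 0.275)
  expect_error(predict(sen, -1), "non-negative")
})

test_that("yield standard errors propagate the vcov by the delta method", {
  cv <- lq_curve(alpha = 1, beta = 1, C = 1)
  cv$vcov <- diag(3)
  dimnames(cv$vcov) <- dimnames(vcov(lq_curve(1, 1)))
  p <- predict(cv, 2, se.fit = TRUE)
  expect_equal(p$se.fit, sqrt(21), tolerance = 1e-12)

  cv$vcov[] <- 0
  expect_equal(predict(cv, c(0, 1, 5), se.fit = TRUE)$se.fit, rep(0, 3))

  cv$vcov <- diag(c(2, 3, 4))
  dimnames(cv$vcov) <- dimnames(vcov(lq_curve(1, 1)))
  expect_equal(predict(cv, 1, se.fit = TRUE)$se.fit, sqrt(9))

  cv$vcov <- matrix(c(1, 2, 0, 2, 1, 0, 0, 0, 1), 3)
  expect_error(predict(cv, 1, se.fit = TRUE), "positive semi-definite")
})

test_that("yield is monotone in dose for non-negative coefficients", {
  set.seed(77)
  for (i in 1:20) {
    cv <- lq_curve(alpha = runif(1, 0, 0.5), beta = runif(1, 0, 0.2),
                   C = runif(1, 0, 0.01))
    y <- predict(cv, seq(0, 10, by = 0.25))
    expect_true(all(diff(y) >= 0))
  }
})

test_that("coefficients never go negative and boundaries are flagged", {
  # strongly concave data: beta wants to be negative, gets pinned at 0
  D <- c(0.5, 1, 2, 4)
  n <- rep(1000, 4)
  x <- round(1000 * (0.5 * D - 0.04 * D^2))
  fit <- lq_fit_points(D, n, x)
  expect_true(all(coef(fit) >= 0))
  expect_true(fit$boundary[["beta"]])
  expect_warning(alpha_beta_ratio(fit), "undefined")
})

test_that("formula and data-frame interfaces agree", {
  sp <- cohort_preset("senegal_africa", cells_per_dose = 500, seed = 9)
  tal <- simulate_tally(sp)
  f1 <- lq_fit(tal, endpoint = "dicentrics")
  tal$count <- tal$dic
  f2 <- lq_fit(count ~ dose_gy, data = tal)
  expect_equal(coef(f1), coef(f2))
  expect_equal(vcov(f1), vcov(f2))
  # dicentrics_rings endpoint really fits dic + cring
  f3 <- lq_fit(tal, endpoint = "dicentrics_rings")
  tal$count <- tal$dic + tal$cring
  f4 <- lq_fit(count ~ dose_gy, data = tal)
  expect_equal(coef(f3), coef(f4))
})

test_that("the quasi-Poisson scale is Pearson-based and floored", {
  set.seed(404)
  inst <- random_fit_instance()
  fit <- lq_fit_points(inst$D, inst$n, inst$x, scale_floor = 0)
  mu <- fitted(fit)
  free <- sum(!fit$boundary)
  pearson <- sum((inst$x - mu)^2 / mu) / (length(mu) - free)
  expect_equal(fit$dispersion_raw, pearson)
  fit1 <- lq_fit_points(inst$D, inst$n, inst$x, scale_floor = 1)
  expect_gte(fit1$dispersion, 1)
  expect_equal(fit1$dispersion, max(1, pearson))
  # covariance scales linearly with the dispersion used
  if (fit$dispersion > 0) {
    expect_equal(vcov(fit1) / fit1$dispersion,
                 vcov(fit) / fit$dispersion, tolerance = 1e-8)
  }
})

test_that("fit methods are coherent", {
  sp <- cohort_preset("all_african", cells_per_dose = 1000, seed = 21)
  fit <- lq_fit(simulate_tally(sp), endpoint = "dsb")
  expect_s3_class(fit, "lq_fit")
  expect_equal(length(residuals(fit)), 5L)
  expect_equal(residuals(fit, "response"),
               fit$data$counts - fitted(fit))
  ci <- confint(fit, level = 0.95)
  expect_true(all(ci[, "lower"] <= coef(fit)))
  expect_true(all(ci[, "upper"] >= coef(fit)))
  s1 <- simulate(fit, nsim = 2, seed = 5)
  s2 <- simulate(fit, nsim = 2, seed = 5)
  expect_identical(s1, s2)
  tab <- curve_table(list(all_african = fit))
  expect_equal(tab$label, "all_african")
  expect_equal(tab$alpha_beta, round(coef(fit)[["alpha"]] /
                                       coef(fit)[["beta"]], 2))
  expect_output(print(fit), "Linear-quadratic")
  expect_output(print(summary(fit)), "Dispersion scale")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})
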