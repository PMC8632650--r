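# Synthetic cohort generator.

test_that("zero yields give all-zero score tables", {
  sp <- cohort_spec(cells_per_dose = 50, seed = 1)
  scores <- simulate_cohort(sp)
  expect_equal(nrow(scores), 50 * 5)
  expect_true(all(scores[, aberration_classes()] == 0))
  expect_true(all(scores$centromere_count == 46))
})

test_that("identical spec and seed reproduce identical tables", {
  sp <- cohort_preset("senegal_africa", cells_per_dose = 100, seed = 42)
  s1 <- simulate_cohort(sp)
  s2 <- simulate_cohort(sp)
  expect_identical(s1, s2)
  t1 <- simulate_tally(sp)
  t2 <- simulate_tally(sp)
  expect_identical(t1, t2)
  # and a different seed does not
  sp2 <- cohort_preset("senegal_africa", cells_per_dose = 100, seed = 43)
  expect_false(identical(simulate_cohort(sp2), s1))
})

test_that("simulated mean dicentric yield tracks the preset curve at 4 Gy", {
  sp <- cohort_preset("senegal_africa", doses = 4, cells_per_dose = 10000,
                      seed = 2024)
  scores <- simulate_cohort(sp)
  truth <- 0.168 * 4 + 0.061 * 16  # 1.648 dicentrics per cell
  expect_lt(abs(mean(scores$dic) - truth), 3 * sqrt(truth / 10000) *
              sqrt(1.3))  # preset applies dispersion 1.3 at 4 Gy
})

test_that("4-telomere fragments pair 1:1 with dicentrics and rings", {
  sp <- cohort_preset("caucasian_europe", cells_per_dose = 300, seed = 6)
  scores <- simulate_cohort(sp)
  expect_equal(scores$ace_4tel, scores$dic + scores$cring)
  # so the DSB tally closes exactly over the weighted classes
  tal <- tally_scores(scores)
  bd <- count_dsb(tal)
  expect_equal(bd$total_dsb,
               2 * (tal$dic + tal$cring) + tal$ace_2tel +
                 2 * tal$ace_0tel + tal$teldel)
})

test_that("independent coupling draws 4-telomere fragments on their own", {
  y <- cytodose:::empty_yields()
  y["dic", ] <- c(0, 0.1, 0.05)
  y["ace_4tel", ] <- c(0, 0.1, 0.05)
  sp <- cohort_spec(class_yields = y, cells_per_dose = 500, seed = 13,
                    coupling = "independent")
  scores <- simulate_cohort(sp)
  expect_false(identical(scores$ace_4tel, scores$dic + scores$cring))
})

test_that("African background can never produce a dicentric", {
  sp <- cohort_preset("senegal_africa", doses = 0, cells_per_dose = 12450,
                      seed = 99)
  bg <- simulate_background(sp)
  expect_equal(sum(bg$dic), 0)
  expect_equal(nrow(bg), 12450)
  # but the deletion-class background is present in expectation
  expect_gt(sum(count_dsb(tally_scores(bg))$total_dsb), 0)
})

test_that("Caucasian background reproduces ~6 dicentrics per 5200 cells", {
  totals <- vapply(1:30, function(s) {
    sp <- cohort_preset("caucasian_europe", doses = 0,
                        cells_per_dose = 5200, seed = 1000 + s)
    sum(simulate_tally(sp)$dic)
  }, 0)
  expect_lt(abs(mean(totals) - 6), 1.5)  # se of the mean ~ 0.45
})

test_that("invalid specs are rejected", {
  expect_error(cohort_spec(cells_per_dose = 0), "cells_per_dose")
  y <- cytodose:::empty_yields()
  y["dic", "alpha"] <- -0.1
  expect_error(cohort_spec(class_yields = y), "negative yield")
  expect_error(cohort_spec(dispersion = 0.5), "dispersion")
  sp <- cohort_preset("senegal_africa", cells_per_dose = 10, seed = 1)
  expect_error(simulate_background(sp), "doses = 0")
})

test_that("contaminated cells fail the analyzability filter downstream", {
  sp <- cohort_preset("all_african", cells_per_dose = 400, seed = 77,
                      contamination = 0.2)
  scores <- simulate_cohort(sp)
  expect_gt(sum(scores$centromere_count != 46), 0)
  tal <- tally_scores(scores, drop_incomplete = TRUE)
  expect_equal(sum(tal$n_cells),
               sum(scores$centromere_count == 46))
})

test_that("aggregate fast path matches per-cell tallies in distribution", {
  sp <- function(seed) cohort_preset("senegal_africa",
                                     cells_per_dose = 400, seed = seed)
  dic4_cells <- vapply(1:40, function(s) {
    sc <- simulate_cohort(sp(s))
    sum(sc$dic[sc$dose_gy == 4])
  }, 0)
  dic4_agg <- vapply(101:140, function(s)
    simulate_tally(sp(s))$dic[5], 0)
  truth <- 400 * 1.648
  # both paths are unbiased for n * lambda
  se <- sqrt(1.3 * truth / 40)
  expect_lt(abs(mean(dic4_cells) - truth), 4 * se)
  expect_lt(abs(mean(dic4_agg) - truth), 4 * se)
})

test_that("fit on a simulated cohort recovers the generating curve", {
  sp <- cohort_preset("senegal_africa", cells_per_dose = 2000, seed = 321)
  fit <- lq_fit(tally_scores(simulate_cohort(sp)),
                endpoint = "dicentrics")
  se <- sqrt(diag(vcov(fit)))
  expect_lt(abs(coef(fit)[["alpha"]] - 0.168), 3 * se[["alpha"]])
  expect_lt(abs(coef(fit)[["beta"]] - 0.061), 3 * se[["beta"]])
})

test_that("overdispersion shows up only where the spec puts it", {
  set.seed(505)
  y <- cytodose:::empty_yields()
  y["dic", ] <- c(0, 0.2, 0.1)
  sp <- cohort_spec(class_yields = y, doses = c(1, 4),
                    cells_per_dose = 2000, dispersion = c(1, 2),
                    seed = 640)
  scores <- simulate_cohort(sp)
  d1 <- dispersion_stats(scores$dic[scores$dose_gy == 1])
  d4 <- dispersion_stats(scores$dic[scores$dose_gy == 4])
  expect_lt(abs(d1$u), 1.96)
  expect_gt(d4$u, 1.96)
})

test_that("cohort specs round-trip through YAML", {
  sp <- cohort_preset("senegal_europe", cells_per_dose = 123, seed = 5,
                      contamination = 0.1)
  f <- tempfile(fileext = ".yaml")
  write_cohort_spec(sp, f)
  back <- read_cohort_spec(f)
  expect_equal(back$class_yields, sp$class_yields, tolerance = 1e-12)
  expect_equal(back$doses, sp$doses)
  expect_equal(back$seed, sp$seed)
  expect_identical(simulate_cohort(back), simulate_cohort(sp))
  unlink(f)
})
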