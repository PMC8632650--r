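# Between-group comparisons: per-cell distributions (Kruskal-Wallis),
# aggregate rates (exact conditional Poisson test), and fitted curves
# (Wald contrast on the coefficients).

comparison_result <- function(test_name, statistic, p_value, group_ids,
                              dose_gy = NA_real_, endpoint = NA_character_,
                              detail = NULL) {
  structure(list(test_name = test_name, statistic = statistic,
                 p_value = p_value, group_ids = group_ids,
                 dose_gy = dose_gy, endpoint = endpoint, detail = detail),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, digits = 4, ...) {
  cat(sprintf("%s: statistic = %.6g, p = %.4g\n", x$test_name,
              x$statistic, x$p_value))
  cat("  groups:", paste(x$group_ids, collapse = " vs "))
  if (!is.na(x$dose_gy)) cat(sprintf(";  dose %g Gy", x$dose_gy))
  if (!is.na(x$endpoint)) cat(";  endpoint", x$endpoint)
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.comparison_result <- function(x, ...) {
  data.frame(test_name = x$test_name, statistic = x$statistic,
             p_value = x$p_value,
             groups = paste(x$group_ids, collapse = "|"),
             dose_gy = x$dose_gy, endpoint = x$endpoint,
             stringsAsFactors = FALSE)
}

#' Kruskal-Wallis comparison of per-cell count distributions
#'
#' Rank-based comparison of two or more samples of per-cell aberration
#' counts (tie-corrected H statistic, chi-square approximation with
#' groups - 1 degrees of freedom). Typically applied to matched doses
#' across donor groups; it can equally take per-donor mean yields as the
#' "samples" for a donor-level comparison.
#'
#' @param samples A list of numeric vectors, one per group (each of
#'   length >= 2).
#' @param group_ids Optional group labels; defaults to list names or
#'   `group_1`, `group_2`, ...
#' @param dose_gy,endpoint Optional annotations carried into the result.
#' @return A `"comparison_result"` with `test_name = "kruskal_wallis"`.
#'   When every observation is identical across all groups the statistic
#'   is 0 and p = 1.
#' @export
compare_distributions <- function(samples, group_ids = NULL,
                                  dose_gy = NA_real_,
                                  endpoint = NA_character_) {
  if (!is.list(samples) || length(samples) < 2L) {
    stop("at least two groups are required", call. = FALSE)
  }
  if (any(vapply(samples, length, 0L) < 2L)) {
    stop("every group needs at least 2 observations", call. = FALSE)
  }
  if (is.null(group_ids)) {
    group_ids <- if (!is.null(names(samples))) names(samples) else
      paste0("group_", seq_along(samples))
  }
  pooled <- unlist(samples)
  if (length(unique(pooled)) == 1L) {
    return(comparison_result("kruskal_wallis", 0, 1, group_ids, dose_gy,
                             endpoint))
  }
  kt <- kruskal.test(samples)
  comparison_result("kruskal_wallis", unname(kt$statistic),
                    unname(kt$p.value), group_ids, dose_gy, endpoint,
                    detail = list(df = unname(kt$parameter)))
}

#' Exact conditional comparison of two Poisson rates
#'
#' Tests equality of two aberration rates given counts over different
#' numbers of scored cells. Conditional on the total count, the first
#' count is Binomial(total, cells_a / (cells_a + cells_b)) under the
#' null, so the exact binomial test applies -- exact even at zero
#' counts, where asymptotic rate tests fail. Two-sided p by the
#' minimum-likelihood method (the default of [stats::binom.test()]) or
#' by doubling the smaller tail.
#'
#' @param count_a,cells_a,count_b,cells_b Counts and cells scored for
#'   the two groups (cells > 0).
#' @param group_ids Labels for the two groups.
#' @param two_sided `"minlik"` (default) or `"double"`.
#' @param dose_gy,endpoint Optional annotations.
#' @return A `"comparison_result"` with `test_name = "rate_test"`,
#'   `statistic` = observed `count_a`. Both counts zero gives p = 1.
#' @examples
#' compare_rates(6, 5200, 0, 12450)  # p ~ 6.5e-4
#' @export
compare_rates <- function(count_a, cells_a, count_b, cells_b,
                          group_ids = c("a", "b"),
                          two_sided = c("minlik", "double"),
                          dose_gy = NA_real_, endpoint = NA_character_) {
  two_sided <- match.arg(two_sided)
  for (v in list(count_a, count_b)) {
    if (length(v) != 1L || is.na(v) || v < 0 || v != round(v)) {
      stop("counts must be single non-negative integers", call. = FALSE)
    }
  }
  if (cells_a <= 0 || cells_b <= 0) {
    stop("cells scored must be positive on both sides", call. = FALSE)
  }
  total <- count_a + count_b
  if (total == 0) {
    return(comparison_result("rate_test", count_a, 1, group_ids, dose_gy,
                             endpoint))
  }
  p0 <- cells_a / (cells_a + cells_b)
  p <- if (two_sided == "minlik") {
    binom.test(count_a, total, p = p0)$p.value
  } else {
    lo <- pbinom(count_a, total, p0)
    hi <- pbinom(count_a - 1, total, p0, lower.tail = FALSE)
    min(1, 2 * min(lo, hi))
  }
  comparison_result("rate_test", count_a, p, group_ids, dose_gy, endpoint,
                    detail = list(total = total, null_prob = p0,
                                  method = two_sided))
}

#' Wald comparison of two fitted curves
#'
#' Chi-square test (2 degrees of freedom) on the difference of the
#' (alpha, beta) coefficient vectors of two curves sharing an endpoint,
#' using the pooled variance-covariance matrix. Complements the
#' distribution-level tests with a curve-level contrast.
#'
#' @param curve_a,curve_b `"lq_curve"`/`"lq_fit"` objects with the same
#'   endpoint and available vcov.
#' @param group_ids Labels for the two curves.
#' @return A `"comparison_result"` with `test_name = "curve_wald"`.
#' @export
compare_curves <- function(curve_a, curve_b, group_ids = c("a", "b")) {
  if (!identical(curve_a$endpoint, curve_b$endpoint)) {
    stop("curves measure different endpoints: ", curve_a$endpoint,
         " vs ", curve_b$endpoint, call. = FALSE)
  }
  idx <- c("alpha", "beta")
  d <- coef(curve_a)[idx] - coef(curve_b)[idx]
  Vp <- vcov(curve_a)[idx, idx] + vcov(curve_b)[idx, idx]
  if (all(Vp == 0)) {
    stop("no variance-covariance information on either curve",
         call. = FALSE)
  }
  if (all(d == 0)) {
    return(comparison_result("curve_wald", 0, 1, group_ids,
                             endpoint = curve_a$endpoint))
  }
  W <- drop(t(d) %*% solve(Vp) %*% d)
  comparison_result("curve_wald", W, pchisq(W, df = 2, lower.tail = FALSE),
                    group_ids, endpoint = curve_a$endpoint,
                    detail = list(df = 2))
}
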