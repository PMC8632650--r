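# Dispersion diagnostics for per-cell aberration counts, and exact
# Poisson confidence intervals for aggregate counts.

#' Dispersion index and Papworth u statistic
#'
#' For per-cell aberration counts the variance-to-mean ratio (dispersion
#' index, sigma^2/y-bar) is 1 under a Poisson distribution. The Papworth
#' u statistic standardises its departure from 1:
#' `u = (DI - 1) * sqrt((N - 1) / (2 * (1 - 1/X)))`
#' with `N` cells and `X` total aberrations; `|u| > 1.96` flags a
#' significant departure at the 5% level (u > 1.96 overdispersion, as
#' expected e.g. for partial-body exposure or high-dose clustering;
#' u < -1.96 underdispersion).
#'
#' @param counts Integer vector of per-cell aberration counts (N >= 2).
#' @return An object of class `"dispersion_stats"`: a list with
#'   `n_cells`, `total`, `mean`, `variance` (N-1 denominator),
#'   `dispersion_index`, `u` (`NA` when fewer than 2 aberrations were
#'   scored, where the statistic is undefined), and `poisson_rejected`
#'   (`|u| > 1.96`).
#' @examples
#' dispersion_stats(c(rep(0, 50), rep(2, 50)))
#' @export
dispersion_stats <- function(counts) {
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  N <- length(counts)
  if (N < 2L) stop("at least 2 cells are required", call. = FALSE)
  X <- sum(counts)
  m <- X / N
  v <- var(counts)
  di <- if (m > 0) v / m else NA_real_
  u <- if (X >= 2 && !is.na(di)) {
    (di - 1) * sqrt((N - 1) / (2 * (1 - 1 / X)))
  } else NA_real_
  structure(list(n_cells = N, total = X, mean = m, variance = v,
                 dispersion_index = di, u = u,
                 poisson_rejected = !is.na(u) && abs(u) > 1.96),
            class = "dispersion_stats")
}

#' @export
print.dispersion_stats <- function(x, digits = 4, ...) {
  cat("Per-cell count dispersion\n")
  cat(sprintf("  N = %d cells, %d aberrations; mean %.4g, variance %.4g\n",
              x$n_cells, x$total, x$mean, x$variance))
  if (is.na(x$u)) {
    cat(sprintf("  dispersion index %s; u undefined (fewer than 2 events)\n",
                if (is.na(x$dispersion_index)) "undefined" else
                  signif(x$dispersion_index, digits)))
  } else {
    cat(sprintf("  dispersion index %.4g, u = %.4g (%s)\n",
                x$dispersion_index, x$u,
                if (x$poisson_rejected) "departs from Poisson at 5%"
                else "consistent with Poisson"))
  }
  invisible(x)
}

#' Exact (Garwood) Poisson confidence interval
#'
#' The classical exact interval for a Poisson mean given an observed
#' count `x`, from chi-square quantiles:
#' lower = qchisq(a/2, 2x)/2 (0 when x = 0),
#' upper = qchisq(1 - a/2, 2x + 2)/2, with a = 1 - conf.
#' Guaranteed coverage at least `conf` (conservatively).
#'
#' @param x Non-negative integer count(s); vectorised.
#' @param conf Confidence level in (0, 1); default 0.95.
#' @return A data frame with columns `x`, `lower`, `upper`.
#' @examples
#' exact_poisson_ci(c(0, 10))
#' @export
exact_poisson_ci <- function(x, conf = 0.95) {
  if (anyNA(x) || any(x < 0) || any(x != round(x))) {
    stop("x must be non-negative integer(s)", call. = FALSE)
  }
  if (!is.numeric(conf) || length(conf) != 1L || conf <= 0 || conf >= 1) {
    stop("conf must be a single number in (0, 1)", call. = FALSE)
  }
  a <- 1 - conf
  lower <- ifelse(x == 0, 0, qchisq(a / 2, 2 * x) / 2)
  upper <- qchisq(1 - a / 2, 2 * x + 2) / 2
  data.frame(x = x, lower = lower, upper = upper)
}
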