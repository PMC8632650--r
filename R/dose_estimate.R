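# Dose estimation: invert a calibrated linear-quadratic curve at an
# observed yield, with uncertainty bounds by Merkle's method -- the
# intersection of the exact Poisson interval of the count with the Wald
# confidence envelope of the calibration curve.

#' Invert a linear-quadratic yield curve
#'
#' Solves `C + alpha*D + beta*D^2 = y` for the non-negative dose:
#' `D = (-alpha + sqrt(alpha^2 + 4*beta*(y - C))) / (2*beta)` when
#' `beta > 0`, `(y - C)/alpha` when `beta = 0`, and 0 whenever the yield
#' does not exceed the background `C`.
#'
#' @param curve An `"lq_curve"` or `"lq_fit"`.
#' @param y Observed yield(s) per cell; vectorised.
#' @return Dose(s) in Gy.
#' @examples
#' cv <- lq_curve(alpha = 0.168, beta = 0.061)
#' invert_curve(cv, 1.648)  # 4 Gy
#' @export
invert_curve <- function(curve, y) {
  cf <- coef(curve)
  C <- cf[["C"]]; a <- cf[["alpha"]]; b <- cf[["beta"]]
  if (a == 0 && b == 0) {
    stop("curve has alpha = beta = 0: no dose information", call. = FALSE)
  }
  if (anyNA(y) || any(y < 0)) stop("yields must be non-negative",
                                   call. = FALSE)
  out <- numeric(length(y))
  excess <- y - C
  pos <- excess > 0
  if (b > 0) {
    out[pos] <- (-a + sqrt(a^2 + 4 * b * excess[pos])) / (2 * b)
  } else {
    out[pos] <- excess[pos] / a
  }
  out
}

#' Estimate absorbed dose from an aberration count
#'
#' Point estimate by inverting the calibration curve at the observed
#' yield `observed_count / n_cells`; uncertainty bounds by Merkle's
#' method. The lower dose bound is where the *upper* curve envelope
#' `Y(D) + z * SE(D)` crosses the lower exact-Poisson (Garwood) bound of
#' the count (per cell); the upper dose bound is where the *lower*
#' envelope `Y(D) - z * SE(D)` crosses the Garwood upper bound. Both
#' crossings are found by bracketed root finding on `[0, d_max]`. An
#' unsolvable lower bound clamps to 0; an unsolvable upper bound is
#' reported at `d_max` with `open_upper = TRUE`.
#'
#' @param curve An `"lq_curve"` or `"lq_fit"` with its
#'   variance-covariance matrix.
#' @param observed_count Total aberrations observed (non-negative
#'   integer).
#' @param n_cells Cells scored (>= 1).
#' @param conf_count Confidence level of the Garwood interval on the
#'   count (default 0.95). `0` is accepted as the degenerate "take the
#'   count at face value" interval.
#' @param conf_curve Confidence level of the curve envelope (default
#'   0.95).
#' @param d_max Upper end of the root-finding bracket in Gy (default 10).
#'   Estimates beyond the calibration range carry an `extrapolated`
#'   warning flag.
#' @return An object of class `"dose_estimate"`: a list with `dose_gy`,
#'   `lower_gy`, `upper_gy`, `observed_count`, `n_cells`,
#'   `observed_yield`, `conf_count`, `conf_curve`, `curve_endpoint`,
#'   `open_upper`, `extrapolated`.
#' @examples
#' cv <- lq_curve(alpha = 0.168, beta = 0.061,
#'                se_alpha = 0.018, se_beta = 0.006,
#'                cov_alpha_beta = -1e-4)
#' estimate_dose(cv, observed_count = 165, n_cells = 100)
#' @export
estimate_dose <- function(curve, observed_count, n_cells,
                          conf_count = 0.95, conf_curve = 0.95,
                          d_max = 10) {
  if (length(observed_count) != 1L || is.na(observed_count) ||
      observed_count < 0 || observed_count != round(observed_count)) {
    stop("observed_count must be a single non-negative integer",
         call. = FALSE)
  }
  if (length(n_cells) != 1L || is.na(n_cells) || n_cells < 1) {
    stop("n_cells must be a single count >= 1", call. = FALSE)
  }
  if (conf_curve <= 0 || conf_curve >= 1) {
    stop("conf_curve must lie in (0, 1)", call. = FALSE)
  }
  yield <- observed_count / n_cells
  point <- invert_curve(curve, yield)

  if (identical(conf_count, 0)) {
    ci <- c(observed_count, observed_count)
  } else {
    g <- exact_poisson_ci(observed_count, conf = conf_count)
    ci <- c(g$lower, g$upper)
  }
  y_lo <- ci[1L] / n_cells
  y_hi <- ci[2L] / n_cells

  z <- qnorm(1 - (1 - conf_curve) / 2)
  env_hi <- function(D) {
    p <- predict(curve, D, se.fit = TRUE)
    p$fit + z * p$se.fit
  }
  env_lo <- function(D) {
    p <- predict(curve, D, se.fit = TRUE)
    p$fit - z * p$se.fit
  }

  # lower dose bound: upper envelope meets the count's lower limit
  lower <- if (env_hi(0) >= y_lo) 0 else if (env_hi(d_max) < y_lo) {
    # even the envelope at d_max cannot reach the lower yield limit
    d_max
  } else {
    uniroot(function(D) env_hi(D) - y_lo, c(0, d_max),
            tol = 1e-9)$root
  }

  # upper dose bound: lower envelope meets the count's upper limit
  open_upper <- FALSE
  upper <- if (env_lo(d_max) < y_hi) {
    open_upper <- TRUE
    d_max
  } else if (env_lo(0) >= y_hi) 0 else {
    uniroot(function(D) env_lo(D) - y_hi, c(0, d_max), tol = 1e-9)$root
  }

  lower <- min(lower, point)
  upper <- max(upper, point)

  cal_max <- if (!is.null(curve$data)) max(curve$data$dose_gy) else d_max
  structure(list(dose_gy = point, lower_gy = lower, upper_gy = upper,
                 observed_count = observed_count, n_cells = n_cells,
                 observed_yield = yield, conf_count = conf_count,
                 conf_curve = conf_curve,
                 curve_endpoint = curve$endpoint,
                 open_upper = open_upper,
                 extrapolated = point > cal_max),
            class = "dose_estimate")
}

#' @export
print.dose_estimate <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Dose estimate (%s): %.3f Gy  [%.3f, %.3f]%s\n",
    x$curve_endpoint, x$dose_gy, x$lower_gy, x$upper_gy,
    if (x$open_upper) " (upper bound open)" else ""))
  cat(sprintf(
    "  from %d aberrations in %d cells (yield %.4g/cell); count CI %g%%, curve envelope %g%%\n",
    x$observed_count, x$n_cells, x$observed_yield,
    100 * x$conf_count, 100 * x$conf_curve))
  if (x$extrapolated) {
    cat("  warning: estimate lies beyond the calibration range\n")
  }
  invisible(x)
}

#' Dose estimates from several endpoints at once
#'
#' Applies [estimate_dose()] to a single-row tally for each supplied
#' calibration curve, reading off the count matching each curve's
#' endpoint (dicentrics; dicentrics + centric rings; total DSB from
#' [count_dsb()]).
#'
#' @param curves A list of `"lq_curve"`/`"lq_fit"` objects (any mix of
#'   endpoints).
#' @param tally A one-row tally data frame.
#' @param aring_weight DSB weight for acentric rings (see
#'   [count_dsb()]).
#' @param ... Passed to [estimate_dose()].
#' @return A named list of `"dose_estimate"` objects, one per curve.
#' @export
estimate_dose_multi <- function(curves, tally, aring_weight = 2, ...) {
  if (inherits(curves, "lq_curve")) curves <- list(curves)
  if (length(curves) == 0L) return(list())
  validate_tally(tally)
  if (nrow(tally) != 1L) stop("tally must have exactly one row",
                              call. = FALSE)
  counts <- c(dicentrics = tally$dic,
              dicentrics_rings = tally$dic + tally$cring,
              dsb = count_dsb(tally, aring_weight)$total_dsb)
  out <- lapply(curves, function(cv) {
    if (!cv$endpoint %in% names(counts)) {
      stop("no count available for endpoint '", cv$endpoint, "'",
           call. = FALSE)
    }
    estimate_dose(cv, counts[[cv$endpoint]], tally$n_cells, ...)
  })
  names(out) <- vapply(curves, function(cv) cv$endpoint, "")
  out
}
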