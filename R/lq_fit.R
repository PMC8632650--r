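# Linear-quadratic calibration by quasi-Poisson maximum likelihood.
#
# Model: per-cell yield Y(D) = C + alpha*D + beta*D^2; the aberration
# count at dose D over n cells is Poisson with mean n * Y(D) (identity
# link on the yield, cells scored as multiplicative exposure). The MLE is
# found by Fisher scoring with an active-set treatment of the
# non-negativity constraints C, alpha, beta >= 0; the covariance of the
# estimates is the inverse Fisher information scaled by the Pearson
# dispersion estimate (quasi-Poisson), floored at `scale_floor`.

#' Construct a dose-response curve from known coefficients
#'
#' Builds an `"lq_curve"` object from published or otherwise externally
#' obtained linear-quadratic coefficients, e.g. a laboratory's reference
#' calibration curve, so it can be used for prediction and dose
#' estimation exactly like a freshly fitted curve.
#'
#' @param alpha Linear coefficient (yield per cell per Gy).
#' @param beta Quadratic coefficient (per Gy^2).
#' @param C Background yield per cell at 0 Gy (default 0).
#' @param se_alpha,se_beta,se_C Standard errors (default 0 = treated as
#'   known exactly).
#' @param cov_alpha_beta Covariance of `alpha` and `beta` (default 0).
#' @param endpoint Which aberration endpoint the curve describes.
#' @param dispersion Quasi-Poisson dispersion scale attached to the
#'   curve (default 1).
#' @return An object of class `"lq_curve"`.
#' @seealso [lq_fit()] to estimate a curve from counts.
#' @export
lq_curve <- function(alpha, beta, C = 0,
                     se_alpha = 0, se_beta = 0, se_C = 0,
                     cov_alpha_beta = 0,
                     endpoint = c("dicentrics", "dicentrics_rings", "dsb"),
                     dispersion = 1) {
  endpoint <- match.arg(endpoint)
  stopifnot(is.finite(alpha), is.finite(beta), is.finite(C),
            alpha >= 0, beta >= 0, C >= 0,
            se_alpha >= 0, se_beta >= 0, se_C >= 0, dispersion >= 0)
  V <- matrix(0, 3L, 3L, dimnames = list(c("C", "alpha", "beta"),
                                         c("C", "alpha", "beta")))
  diag(V) <- c(se_C^2, se_alpha^2, se_beta^2)
  V["alpha", "beta"] <- V["beta", "alpha"] <- cov_alpha_beta
  structure(list(
    coefficients = c(C = C, alpha = alpha, beta = beta),
    vcov = V,
    endpoint = endpoint,
    dispersion = dispersion),
    class = "lq_curve")
}

#' Fit a linear-quadratic dose-response curve
#'
#' Estimates the yield curve `Y(D) = C + alpha*D + beta*D^2` from
#' per-dose aberration counts by maximum likelihood under a quasi-Poisson
#' model: the count at dose `D` over `n` cells is Poisson with mean
#' `n * Y(D)`, and the covariance of the estimates is scaled by the
#' Pearson dispersion. Coefficients are constrained non-negative
#' (physical yields); a coefficient driven to the boundary is pinned at 0
#' and the remaining parameters re-profiled.
#'
#' `lq_fit()` is generic. The data-frame method takes a tally table (see
#' [tally_scores()]) and an `endpoint` naming which count to fit:
#' dicentrics, dicentrics plus centric rings, or total DSB from
#' [count_dsb()]. The formula method takes `count ~ dose` with a `cells`
#' argument naming the exposure column.
#'
#' @param x A tally data frame, or a formula `count ~ dose`.
#' @param ... Passed on to the workhorse (e.g. `scale_floor`,
#'   `max_iter`, `tol`).
#' @return An object of class `c("lq_fit", "lq_curve")` with
#'   `coefficients` (C, alpha, beta), `vcov` (3x3, scaled by the
#'   dispersion), `dispersion` (scale used), `dispersion_raw` (Pearson
#'   estimate before flooring), `boundary` (which coefficients were
#'   pinned at 0), `degenerate` (all counts zero), `converged`,
#'   `iterations`, `loglik`, and the fitting data. Methods: `print`,
#'   `summary`, `coef`, `vcov`, `predict`, `confint`, `residuals`,
#'   `fitted`, `simulate`, `plot`, `logLik`.
#' @examples
#' tal <- data.frame(group_id = "g", dose_gy = c(0, 0.5, 1, 2, 4),
#'                   n_cells = 2000, dic = c(0, 180, 470, 1150, 3300),
#'                   cring = 0, aring = 0, ace_4tel = 0, ace_2tel = 0,
#'                   ace_0tel = 0, teldel = 0)
#' fit <- lq_fit(tal, endpoint = "dicentrics")
#' coef(fit)
#' predict(fit, dose = 3, se.fit = TRUE)
#' @export
lq_fit <- function(x, ...) UseMethod("lq_fit")

#' @rdname lq_fit
#' @param endpoint One of `"dicentrics"`, `"dicentrics_rings"`, `"dsb"`.
#' @param aring_weight DSB weight for acentric rings when
#'   `endpoint = "dsb"`.
#' @export
lq_fit.data.frame <- function(x,
                              endpoint = c("dicentrics", "dicentrics_rings",
                                           "dsb"),
                              aring_weight = 2, ...) {
  validate_tally(x)
  endpoint <- match.arg(endpoint)
  if (length(unique(x$group_id)) > 1L) {
    stop("tally mixes groups: ",
         paste(unique(x$group_id), collapse = ", "),
         "; fit one group at a time", call. = FALSE)
  }
  counts <- switch(endpoint,
                   dicentrics = x$dic,
                   dicentrics_rings = x$dic + x$cring,
                   dsb = count_dsb(x, aring_weight)$total_dsb)
  out <- lq_fit_points(x$dose_gy, x$n_cells, counts, endpoint = endpoint, ...)
  out$call <- match.call()
  out
}

#' @rdname lq_fit
#' @param data Data frame holding the formula variables.
#' @param cells Exposure: a column name in `data` or a numeric vector of
#'   cells scored; defaults to column `n_cells`.
#' @export
lq_fit.formula <- function(x, data, cells = "n_cells",
                           endpoint = c("dicentrics", "dicentrics_rings",
                                        "dsb"), ...) {
  endpoint <- match.arg(endpoint)
  mf <- stats::model.frame(x, data)
  if (ncol(mf) != 2L) stop("formula must be of the form count ~ dose",
                           call. = FALSE)
  counts <- stats::model.response(mf)
  dose <- mf[[2L]]
  n <- if (is.character(cells)) {
    if (!cells %in% names(data)) stop("no column '", cells, "' in data",
                                      call. = FALSE)
    data[[cells]]
  } else cells
  out <- lq_fit_points(dose, n, counts, endpoint = endpoint, ...)
  out$call <- match.call()
  out
}

#' @rdname lq_fit
#' @param dose,n_cells,counts Parallel vectors: dose (Gy), cells scored,
#'   aberration count at each dose point.
#' @param scale_floor Minimum dispersion scale applied to the covariance
#'   (default 1: never report anti-conservative standard errors).
#' @param max_iter,tol Fisher-scoring iteration cap and relative
#'   log-likelihood convergence tolerance.
#' @export
lq_fit_points <- function(dose, n_cells, counts,
                          endpoint = c("dicentrics", "dicentrics_rings",
                                       "dsb"),
                          scale_floor = 1, max_iter = 100L, tol = 1e-10) {
  endpoint <- match.arg(endpoint)
  D <- as.numeric(dose); n <- as.numeric(n_cells); x <- as.numeric(counts)
  if (length(D) != length(n) || length(D) != length(x)) {
    stop("dose, n_cells and counts must have equal length", call. = FALSE)
  }
  if (anyNA(c(D, n, x)) || any(D < 0) || any(n < 1) || any(x < 0)) {
    stop("invalid dose point: doses >= 0, n_cells >= 1, counts >= 0 required",
         call. = FALSE)
  }
  if (length(unique(D)) < 3L) {
    stop("at least 3 distinct doses are needed to fit C, alpha and beta",
         call. = FALSE)
  }

  eng <- lq_engine(D, n, x, scale_floor = scale_floor,
                   max_iter = max_iter, tol = tol)

  fit <- lq_curve(alpha = eng$theta[2L], beta = eng$theta[3L],
                  C = eng$theta[1L], endpoint = endpoint)
  fit$vcov <- eng$vcov
  fit$dispersion <- eng$phi_used
  fit$dispersion_raw <- eng$phi_hat
  fit$data <- data.frame(dose_gy = D, n_cells = n, counts = x)
  fit$fitted.values <- n * as.vector(cbind(1, D, D^2) %*% eng$theta)
  fit$loglik <- eng$loglik
  fit$df.residual <- eng$df
  fit$boundary <- eng$boundary
  fit$degenerate <- eng$degenerate
  fit$converged <- eng$converged
  fit$iterations <- eng$iterations
  fit$call <- match.call()
  class(fit) <- c("lq_fit", "lq_curve")
  if (!fit$converged && !fit$degenerate) {
    warning(sprintf(
      "lq_fit did not converge in %d iterations (last rel. change %.3g)",
      eng$iterations, eng$last_change), call. = FALSE)
  }
  fit
}

# Poisson log-likelihood of counts x with mean n * (V theta); -Inf when a
# positive count sits on a zero or negative mean.
lq_loglik <- function(theta, D, n, x) {
  mu <- n * as.vector(cbind(1, D, D^2) %*% theta)
  if (any(mu < 0)) return(-Inf)
  pos <- mu > 0
  if (any(x[!pos] > 0)) return(-Inf)
  sum(x[pos] * log(mu[pos]) - mu[pos]) - sum(lgamma(x + 1))
}

# solve with an adaptive ridge so near-boundary weight blow-ups cannot
# abort the fit
safe_solve <- function(A, b = NULL) {
  r <- 0
  for (k in 1:20) {
    out <- tryCatch({
      Ar <- A + diag(r, nrow(A))
      if (is.null(b)) solve(Ar) else solve(Ar, b)
    }, error = function(e) NULL)
    if (!is.null(out)) return(out)
    r <- if (r == 0) max(abs(diag(A)), 1) * 1e-14 else r * 100
  }
  stop("singular information matrix", call. = FALSE)
}

lq_engine <- function(D, n, x, scale_floor = 1, max_iter = 100L,
                      tol = 1e-10) {
  V <- cbind(1, D, D^2)
  p <- 3L
  if (all(x == 0)) {
    return(list(theta = c(0, 0, 0),
                vcov = matrix(0, p, p,
                              dimnames = list(c("C", "alpha", "beta"),
                                              c("C", "alpha", "beta"))),
                phi_hat = NA_real_, phi_used = scale_floor,
                loglik = 0, df = length(x) - 0L,
                boundary = c(C = TRUE, alpha = TRUE, beta = TRUE),
                degenerate = TRUE, converged = TRUE, iterations = 0L,
                last_change = 0))
  }

  grad_full <- function(theta) {
    mu <- n * as.vector(V %*% theta)
    r <- ifelse(x == 0, -1, x / pmax(mu, 1e-300) - 1)
    as.vector(crossprod(V, n * r))
  }

  # moment start: weighted least squares on per-cell yields, clipped into
  # the interior
  y <- x / n
  W <- n
  init <- tryCatch(
    as.vector(solve(crossprod(V, V * W), crossprod(V, y * W))),
    error = function(e) rep(sum(x) / sum(n * (1 + D + D^2)), p))
  theta <- pmax(init, 1e-6)

  ll <- lq_loglik(theta, D, n, x)
  yield_scale <- max(sum(x) / sum(n), 1e-6)
  converged <- FALSE
  last_change <- Inf
  it <- 0L
  stalls <- 0L
  for (it in seq_len(max_iter)) {
    g <- grad_full(theta)
    # active set: pinned at zero with no incentive to move inward
    active <- theta <= 0 & g <= 1e-8
    free <- which(!active)
    if (!length(free)) { converged <- TRUE; break }
    mu <- n * as.vector(V %*% theta)
    w <- ifelse(mu > 0, n^2 / mu, 0)
    Vf <- V[, free, drop = FALSE]
    info <- crossprod(Vf, Vf * w)
    step <- safe_solve(info, g[free])
    # damped step with projection onto the non-negative orthant
    t_step <- 1
    repeat {
      cand <- theta
      cand[free] <- pmax(theta[free] + t_step * step, 0)
      llc <- lq_loglik(cand, D, n, x)
      if (is.finite(llc) && llc >= ll - 1e-12) break
      t_step <- t_step / 2
      if (t_step < 1e-10) { cand <- theta; llc <- ll; break }
    }
    g <- grad_full(cand)
    # snap a coefficient sliding geometrically into the boundary to an
    # exact zero (keeps the Fisher weights finite); accept only if the
    # likelihood does not drop
    tiny <- cand > 0 & cand < 1e-8 * yield_scale & g < 0
    if (any(tiny)) {
      snapped <- cand
      snapped[tiny] <- 0
      lls <- lq_loglik(snapped, D, n, x)
      if (is.finite(lls) && lls >= llc - 1e-12 * (1 + abs(llc))) {
        cand <- snapped
        llc <- lls
        g <- grad_full(cand)
      }
    }
    last_change <- abs(llc - ll) / (abs(ll) + 1e-12)
    theta <- cand
    ll <- llc
    # KKT: interior gradients vanish (on the Fisher scale), boundary
    # gradients point outward
    gs <- g / sqrt(pmax(diag(crossprod(V, V * w)), 1))
    kkt <- all(abs(gs[theta > 0]) < 1e-6) && all(g[theta <= 0] <= 1e-6)
    if (last_change < tol) {
      stalls <- stalls + 1L
      if (kkt) { converged <- TRUE; break }
      # no further likelihood progress is possible in double precision;
      # accept the point if the stationarity residual is still small
      if (stalls >= 3L) {
        converged <- all(abs(gs[theta > 0]) < 1e-4) &&
          all(g[theta <= 0] <= 1e-4)
        break
      }
    } else stalls <- 0L
  }

  g <- grad_full(theta)
  boundary <- theta <= 0 & g <= 1e-6
  names(boundary) <- c("C", "alpha", "beta")
  free <- which(!boundary)
  mu <- n * as.vector(V %*% theta)

  # Pearson dispersion over informative points
  pos <- mu > 0
  df <- sum(pos) - length(free)
  phi_hat <- if (df > 0) sum((x[pos] - mu[pos])^2 / mu[pos]) / df else
    NA_real_
  phi_used <- max(scale_floor, phi_hat, na.rm = TRUE)

  vc <- matrix(0, p, p, dimnames = list(c("C", "alpha", "beta"),
                                        c("C", "alpha", "beta")))
  if (length(free)) {
    w <- ifelse(mu > 0, n^2 / mu, 0)
    Vf <- V[, free, drop = FALSE]
    info <- crossprod(Vf, Vf * w)
    vc[free, free] <- phi_used * safe_solve(info)
  }

  list(theta = theta, vcov = vc, phi_hat = phi_hat, phi_used = phi_used,
       loglik = ll, df = max(df, 0L), boundary = boundary,
       degenerate = FALSE, converged = converged, iterations = it,
       last_change = last_change)
}

#' @export
coef.lq_curve <- function(object, ...) object$coefficients

#' @export
vcov.lq_curve <- function(object, ...) object$vcov

#' Ratio of the linear to the quadratic coefficient
#'
#' `alpha/beta` is the dose (Gy) at which the linear and quadratic
#' contributions to the yield are equal, a standard curve-shape summary.
#'
#' @param curve An `"lq_curve"` or `"lq_fit"` object.
#' @return A single number; `NA` with a warning when `beta` is 0.
#' @export
alpha_beta_ratio <- function(curve) {
  cf <- coef(curve)
  if (cf[["beta"]] <= 0) {
    warning("alpha/beta undefined: beta is zero", call. = FALSE)
    return(NA_real_)
  }
  cf[["alpha"]] / cf[["beta"]]
}

#' Predict the yield (and its standard error) at given doses
#'
#' Evaluates `Y(D) = C + alpha*D + beta*D^2`; with `se.fit = TRUE` the
#' delta-method standard error `sqrt(v' Sigma v)` with `v = (1, D, D^2)`
#' is returned alongside, using the curve's variance-covariance matrix.
#'
#' @param object An `"lq_curve"` or `"lq_fit"`.
#' @param dose Vector of doses in Gy (must be non-negative).
#' @param se.fit Also return the standard error of the predicted yield.
#' @param ... Unused.
#' @return A numeric vector of yields, or if `se.fit = TRUE` a list with
#'   components `fit` and `se.fit`.
#' @export
predict.lq_curve <- function(object, dose, se.fit = FALSE, ...) {
  if (missing(dose) && inherits(object, "lq_fit")) dose <- object$data$dose_gy
  if (anyNA(dose) || any(dose < 0)) {
    stop("doses must be non-negative", call. = FALSE)
  }
  cf <- coef(object)
  fit <- cf[["C"]] + cf[["alpha"]] * dose + cf[["beta"]] * dose^2
  if (!se.fit) return(fit)
  Sg <- vcov(object)
  ev <- eigen(Sg, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop("variance-covariance matrix is not positive semi-definite",
         call. = FALSE)
  }
  Vm <- cbind(1, dose, dose^2)
  se <- sqrt(pmax(rowSums((Vm %*% Sg) * Vm), 0))
  list(fit = fit, se.fit = se)
}

#' @export
fitted.lq_fit <- function(object, ...) object$fitted.values

#' @export
logLik.lq_fit <- function(object, ...) {
  structure(object$loglik, df = sum(!object$boundary), class = "logLik")
}

#' @export
residuals.lq_fit <- function(object,
                             type = c("pearson", "deviance", "response"),
                             ...) {
  type <- match.arg(type)
  x <- object$data$counts
  mu <- object$fitted.values
  switch(type,
         response = x - mu,
         pearson = ifelse(mu > 0, (x - mu) / sqrt(mu), 0),
         deviance = {
           d <- 2 * (ifelse(x > 0, x * log(x / pmax(mu, 1e-300)), 0) -
                       (x - mu))
           sign(x - mu) * sqrt(pmax(d, 0))
         })
}

#' @export
confint.lq_fit <- function(object, parm = c("C", "alpha", "beta"),
                           level = 0.95, ...) {
  parm <- match.arg(parm, several.ok = TRUE)
  z <- qnorm(1 - (1 - level) / 2)
  cf <- coef(object)[parm]
  se <- sqrt(diag(vcov(object)))[parm]
  out <- cbind(lower = cf - z * se, upper = cf + z * se)
  rownames(out) <- parm
  out
}

#' @export
simulate.lq_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = .GlobalEnv))
    set.seed(seed)
  }
  mu <- object$fitted.values
  out <- as.data.frame(replicate(nsim, rpois(length(mu), mu)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
print.lq_curve <- function(x, digits = 4, ...) {
  cat("Linear-quadratic yield curve (", x$endpoint, ")\n", sep = "")
  cf <- coef(x)
  se <- sqrt(diag(vcov(x)))
  cat(sprintf("  Y(D) = %s + %s D + %s D^2   [per cell, D in Gy]\n",
              signif(cf[["C"]], digits), signif(cf[["alpha"]], digits),
              signif(cf[["beta"]], digits)))
  cat(sprintf("  SE: C %s, alpha %s, beta %s; dispersion %s\n",
              signif(se[1L], digits), signif(se[2L], digits),
              signif(se[3L], digits), signif(x$dispersion, digits)))
  if (cf[["beta"]] > 0) {
    cat(sprintf("  alpha/beta = %.2f Gy\n", cf[["alpha"]] / cf[["beta"]]))
  }
  invisible(x)
}

#' @export
print.lq_fit <- function(x, digits = 4, ...) {
  NextMethod()
  if (x$degenerate) {
    cat("  degenerate fit: all counts zero\n")
  } else {
    cat(sprintf("  %d dose points; converged in %d iterations\n",
                nrow(x$data), x$iterations))
    if (any(x$boundary)) {
      cat("  pinned at zero:",
          paste(names(x$boundary)[x$boundary], collapse = ", "), "\n")
    }
  }
  invisible(x)
}

#' @export
summary.lq_fit <- function(object, ...) {
  cf <- coef(object)
  se <- sqrt(diag(vcov(object)))
  z <- ifelse(se > 0, cf / se, NA_real_)
  tab <- cbind(Estimate = cf, `Std. Error` = se, `z value` = z,
               `Pr(>|z|)` = 2 * pnorm(abs(z), lower.tail = FALSE))
  structure(list(coefficients = tab,
                 dispersion = object$dispersion,
                 dispersion_raw = object$dispersion_raw,
                 loglik = object$loglik,
                 df.residual = object$df.residual,
                 endpoint = object$endpoint,
                 boundary = object$boundary,
                 degenerate = object$degenerate,
                 alpha_beta = if (cf[["beta"]] > 0)
                   cf[["alpha"]] / cf[["beta"]] else NA_real_,
                 cov_alpha_beta = vcov(object)["alpha", "beta"],
                 call = object$call),
            class = "summary.lq_fit")
}

#' @export
print.summary.lq_fit <- function(x, digits = 4, ...) {
  cat("Quasi-Poisson linear-quadratic calibration (", x$endpoint, ")\n\n",
      sep = "")
  stats::printCoefmat(x$coefficients, digits = digits, na.print = "-")
  cat(sprintf("\nDispersion scale: %.4f (Pearson estimate %.4f)\n",
              x$dispersion,
              if (is.na(x$dispersion_raw)) NA else x$dispersion_raw))
  if (!is.na(x$alpha_beta)) {
    cat(sprintf("alpha/beta: %.2f Gy;  cov(alpha, beta): %.3g\n",
                x$alpha_beta, x$cov_alpha_beta))
  }
  if (any(x$boundary)) {
    cat("Coefficients pinned at zero:",
        paste(names(x$boundary)[x$boundary], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Plot a fitted dose-response curve
#'
#' Observed per-cell yields with exact Poisson (Garwood) error bars and
#' the fitted curve with its delta-method confidence envelope.
#'
#' @param x An `"lq_fit"` object.
#' @param level Confidence level for error bars and envelope.
#' @param ... Passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.lq_fit <- function(x, level = 0.95, ...) {
  d <- x$data
  yield <- d$counts / d$n_cells
  ci <- exact_poisson_ci(d$counts, conf = level)
  dg <- seq(0, max(d$dose_gy), length.out = 101L)
  pr <- predict(x, dg, se.fit = TRUE)
  z <- qnorm(1 - (1 - level) / 2)
  ylim <- range(0, ci$upper / d$n_cells, pr$fit + z * pr$se.fit)
  plot(d$dose_gy, yield, xlab = "Dose (Gy)",
       ylab = paste0("Yield per cell (", x$endpoint, ")"),
       ylim = ylim, pch = 19, ...)
  segments(d$dose_gy, ci$lower / d$n_cells, d$dose_gy,
           ci$upper / d$n_cells)
  lines(dg, pr$fit, col = "grey40", lwd = 2)
  lines(dg, pr$fit + z * pr$se.fit, col = "grey60", lty = 3)
  lines(dg, pmax(pr$fit - z * pr$se.fit, 0), col = "grey60", lty = 3)
  invisible(x)
}

#' Table-style summary of one or more curves
#'
#' Builds the conventional calibration summary table: alpha and beta with
#' their standard errors, the alpha/beta ratio (rounded to two decimals,
#' as customarily printed), and cov(alpha, beta).
#'
#' @param curves A single curve or a (possibly named) list of
#'   `"lq_curve"`/`"lq_fit"` objects.
#' @param labels Optional row labels; defaults to list names.
#' @return A data frame with one row per curve.
#' @export
curve_table <- function(curves, labels = NULL) {
  if (inherits(curves, "lq_curve")) curves <- list(curves)
  if (is.null(labels)) {
    labels <- if (!is.null(names(curves))) names(curves) else
      paste0("curve_", seq_along(curves))
  }
  rows <- lapply(seq_along(curves), function(i) {
    cv <- curves[[i]]
    cf <- coef(cv)
    se <- sqrt(diag(vcov(cv)))
    data.frame(label = labels[i], endpoint = cv$endpoint,
               C = cf[["C"]], alpha = cf[["alpha"]],
               se_alpha = se[["alpha"]], beta = cf[["beta"]],
               se_beta = se[["beta"]],
               alpha_beta = if (cf[["beta"]] > 0)
                 round(cf[["alpha"]] / cf[["beta"]], 2) else NA_real_,
               cov_alpha_beta = vcov(cv)["alpha", "beta"],
               dispersion = cv$dispersion,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
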