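# Synthetic metaphase score tables with the statistical structure the
# calibration assumes: per-cell class counts Poisson (or gamma-mixed
# Poisson for overdispersion) around linear-quadratic mean yields, with
# 4-telomere fragments paired to the dicentrics/rings they accompany.

#' Reference linear-quadratic coefficients for four donor cohorts
#'
#' Calibration coefficients (alpha, beta with standard errors and
#' cov(alpha, beta)) for dicentrics, dicentrics + centric rings, and
#' total DSB in four healthy-donor cohorts: African ancestry (Senegal)
#' living in Africa, all African ancestry living in Africa, African
#' ancestry (Senegal) living in Europe, and Caucasian donors living in
#' Europe. These drive the simulator presets ([cohort_preset()]) and can
#' be turned into curves with [lq_curve()].
#'
#' @return A data frame with columns `group`, `endpoint`, `alpha`,
#'   `se_alpha`, `beta`, `se_beta`, `cov_alpha_beta`.
#' @export
reference_curves <- function() {
  g <- c("senegal_africa", "all_african", "senegal_europe",
         "caucasian_europe")
  rbind(
    data.frame(group = g, endpoint = "dicentrics",
               alpha = c(0.168, 0.103, 0.084, 0.147),
               se_alpha = c(0.018, 0.008, 0.022, 0.040),
               beta = c(0.061, 0.079, 0.122, 0.128),
               se_beta = c(0.006, 0.002, 0.007, 0.013),
               cov_alpha_beta = c(-1e-4, -2.2e-5, -1e-4, -5e-4),
               stringsAsFactors = FALSE),
    data.frame(group = g, endpoint = "dicentrics_rings",
               alpha = c(0.207, 0.107, 0.083, 0.120),
               se_alpha = c(0.065, 0.010, 0.034, 0.043),
               beta = c(0.065, 0.102, 0.146, 0.171),
               se_beta = c(0.008, 0.003, 0.011, 0.013),
               cov_alpha_beta = c(-2e-4, -3e-5, -3e-4, -5e-4),
               stringsAsFactors = FALSE),
    data.frame(group = g, endpoint = "dsb",
               alpha = c(0.512, 0.263, 0.219, 0.277),
               se_alpha = c(0.050, 0.026, 0.111, 0.091),
               beta = c(0.155, 0.257, 0.357, 0.257),
               se_beta = c(0.016, 0.009, 0.369, 0.009),
               cov_alpha_beta = c(-7e-4, -2.4e-3, -3.8e-3, -2e-4),
               stringsAsFactors = FALSE))
}

#' Build an `"lq_curve"` from a reference cohort row
#'
#' @param group One of `"senegal_africa"`, `"all_african"`,
#'   `"senegal_europe"`, `"caucasian_europe"`.
#' @param endpoint One of `"dicentrics"`, `"dicentrics_rings"`, `"dsb"`.
#' @return An `"lq_curve"` (background `C` taken as 0 for African
#'   groups; 6/5200 dicentrics per cell for the Caucasian group when
#'   `endpoint = "dicentrics"`).
#' @export
reference_curve <- function(group, endpoint = "dicentrics") {
  tab <- reference_curves()
  row <- tab[tab$group == group & tab$endpoint == endpoint, ]
  if (nrow(row) != 1L) {
    stop("unknown group/endpoint: ", group, "/", endpoint, call. = FALSE)
  }
  C <- if (group == "caucasian_europe" && endpoint == "dicentrics")
    6 / 5200 else 0
  lq_curve(alpha = row$alpha, beta = row$beta, C = C,
           se_alpha = row$se_alpha, se_beta = row$se_beta,
           cov_alpha_beta = row$cov_alpha_beta, endpoint = endpoint)
}

empty_yields <- function() {
  m <- matrix(0, nrow = 7L, ncol = 3L,
              dimnames = list(aberration_classes(),
                              c("C", "alpha", "beta")))
  as.data.frame(m)
}

# Per-class LQ yields for a preset cohort. The dicentric row carries the
# group's published coefficients exactly; centric rings get the
# (dicentrics+rings) minus dicentrics coefficients, floored at 0; the
# DSB-row surplus beyond 2*(dic+ring) is split between terminal
# deletions, interstitial deletions and telomere deletions in DSB
# proportions `residual_split` (deletion-class yields follow from their
# DSB weights: 1, 2 and 1). Backgrounds: zero dicentrics for African
# groups, 6/5200 per cell for Caucasians; all groups carry a small
# deletion-class background summing to `background_dsb` DSB per cell.
preset_class_yields <- function(group,
                                background_dsb = 0.0017,
                                residual_split = c(ace_2tel = 0.5,
                                                   ace_0tel = 0.25,
                                                   teldel = 0.25)) {
  tab <- reference_curves()
  pick <- function(ep) tab[tab$group == group & tab$endpoint == ep, ]
  dic <- pick("dicentrics"); dr <- pick("dicentrics_rings")
  dsb <- pick("dsb")
  if (nrow(dic) != 1L) stop("unknown preset group: ", group, call. = FALSE)
  y <- empty_yields()
  y["dic", ] <- c(if (group == "caucasian_europe") 6 / 5200 else 0,
                  dic$alpha, dic$beta)
  y["cring", c("alpha", "beta")] <- pmax(0, c(dr$alpha - dic$alpha,
                                              dr$beta - dic$beta))
  resid_a <- max(0, dsb$alpha - 2 * dr$alpha)
  resid_b <- max(0, dsb$beta - 2 * dr$beta)
  w <- residual_split / sum(residual_split)
  # DSB weights of the residual classes
  dw <- c(ace_2tel = 1, ace_0tel = 2, teldel = 1)
  for (cl in names(w)) {
    y[cl, "alpha"] <- w[[cl]] * resid_a / dw[[cl]]
    y[cl, "beta"] <- w[[cl]] * resid_b / dw[[cl]]
    y[cl, "C"] <- w[[cl]] * background_dsb / dw[[cl]]
  }
  y
}

#' Specify a synthetic cohort
#'
#' Bundles everything the simulator needs: the dose schedule, cells per
#' dose, per-class linear-quadratic yields, dispersion, and the seed.
#' Defaults reflect a typical calibration study: doses 0, 0.5, 1, 2 and
#' 4 Gy with about 200 metaphases scored per dose (two slides of ~100).
#'
#' @param group_id Cohort label.
#' @param doses Dose schedule in Gy.
#' @param cells_per_dose Metaphases scored at each dose (>= 1).
#' @param class_yields Data frame (rows = [aberration_classes()],
#'   columns `C`, `alpha`, `beta`) of per-cell LQ yields; defaults to
#'   all-zero.
#' @param dispersion Variance inflation of per-cell counts: 1 = Poisson;
#'   d > 1 = gamma-mixed Poisson with variance `d * mean`. A scalar, or
#'   a vector parallel to `doses` for dose-specific dispersion.
#' @param seed Integer seed; identical specs with identical seeds yield
#'   identical tables.
#' @param coupling `"paired"` (default): each dicentric or centric ring
#'   is accompanied by exactly one 4-telomere fragment, as the scoring
#'   rule pairs them. `"independent"`: `ace_4tel` is drawn from its own
#'   yield row (stress-testing mode).
#' @param contamination Fraction of cells with a centromere count other
#'   than 46 (they fail the analyzability filter); default 0.
#' @param n_donors Number of donors the cells are spread over.
#' @param frailty_sd Standard deviation (log scale) of an optional
#'   per-donor lognormal frailty multiplying all yields; 0 = off.
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(group_id = "cohort",
                        doses = c(0, 0.5, 1, 2, 4),
                        cells_per_dose = 200L,
                        class_yields = empty_yields(),
                        dispersion = 1,
                        seed = NULL,
                        coupling = c("paired", "independent"),
                        contamination = 0,
                        n_donors = 1L,
                        frailty_sd = 0) {
  coupling <- match.arg(coupling)
  stopifnot(length(doses) >= 1L, all(doses >= 0), cells_per_dose >= 1,
            contamination >= 0, contamination < 1, n_donors >= 1,
            frailty_sd >= 0)
  if (!all(aberration_classes() %in% rownames(class_yields))) {
    stop("class_yields must have one row per aberration class",
         call. = FALSE)
  }
  if (!all(c("C", "alpha", "beta") %in% colnames(class_yields))) {
    stop("class_yields needs columns C, alpha, beta", call. = FALSE)
  }
  if (length(dispersion) == 1L) dispersion <- rep(dispersion,
                                                  length(doses))
  if (length(dispersion) != length(doses) || any(dispersion < 1)) {
    stop("dispersion must be >= 1, scalar or one value per dose",
         call. = FALSE)
  }
  for (D in doses) {
    lam <- class_yields$C + class_yields$alpha * D +
      class_yields$beta * D^2
    if (any(lam < 0)) {
      stop(sprintf("negative yield at %g Gy for class %s", D,
                   rownames(class_yields)[which(lam < 0)[1L]]),
           call. = FALSE)
    }
  }
  structure(list(group_id = group_id, doses = doses,
                 cells_per_dose = as.integer(cells_per_dose),
                 class_yields = class_yields[aberration_classes(), ],
                 dispersion = dispersion, seed = seed,
                 coupling = coupling, contamination = contamination,
                 n_donors = as.integer(n_donors),
                 frailty_sd = frailty_sd),
            class = "cohort_spec")
}

#' Preset cohort specifications
#'
#' A [cohort_spec()] whose class yields reproduce one of the four
#' reference cohorts (see [reference_curves()]): the dicentric yields
#' equal the published coefficients exactly, centric rings carry the
#' rings-minus-dicentrics surplus, and the deletion classes absorb the
#' remaining DSB yield (50/25/25 split between terminal deletions,
#' interstitial deletions and telomere deletions). Dispersion is 1
#' (Poisson) at every dose except 1.3 at 4 Gy, where mild
#' overdispersion is the empirical norm.
#'
#' @param group Preset name; see [reference_curves()].
#' @param cells_per_dose,doses,seed,... Overrides passed to
#'   [cohort_spec()].
#' @return A `"cohort_spec"`.
#' @examples
#' sp <- cohort_preset("senegal_africa", cells_per_dose = 200, seed = 1)
#' scores <- simulate_cohort(sp)
#' @export
cohort_preset <- function(group = c("senegal_africa", "all_african",
                                    "senegal_europe", "caucasian_europe"),
                          cells_per_dose = 200L,
                          doses = c(0, 0.5, 1, 2, 4),
                          seed = NULL, ...) {
  group <- match.arg(group)
  disp <- ifelse(doses == 4, 1.3, 1)
  cohort_spec(group_id = group, doses = doses,
              cells_per_dose = cells_per_dose,
              class_yields = preset_class_yields(group),
              dispersion = disp, seed = seed, ...)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("Cohort spec '%s': %d cells at each of %s Gy\n", x$group_id,
              x$cells_per_dose, paste(x$doses, collapse = ", ")))
  cat(sprintf("  dispersion %s; coupling %s; %d donor(s)%s\n",
              paste(x$dispersion, collapse = "/"), x$coupling, x$n_donors,
              if (!is.null(x$seed)) paste0("; seed ", x$seed) else ""))
  invisible(x)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- get0(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv))
        rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  set.seed(seed)
  expr
}

# variance d*lambda: Poisson when d == 1, gamma-mixed Poisson
# (negative binomial, size = lambda/(d-1)) when d > 1
rcount <- function(n, lambda, d) {
  if (lambda == 0) return(integer(n))
  if (d <= 1) rpois(n, lambda) else
    rnbinom(n, mu = lambda, size = lambda / (d - 1))
}

#' Simulate a per-metaphase score table
#'
#' Draws, for each dose and cell, independent per-class counts with mean
#' `C + alpha*D + beta*D^2` (Poisson, or gamma-mixed Poisson when the
#' spec's dispersion exceeds 1). Under the default `"paired"` coupling
#' each dicentric and centric ring is accompanied by exactly one
#' 4-telomere fragment (`ace_4tel = dic + cring` in every cell). All
#' cells carry 46 centromeres unless a contamination fraction is set.
#'
#' @param spec A [cohort_spec()].
#' @return A per-metaphase score data frame (the dialect of
#'   [read_scores()]).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    Y <- spec$class_yields
    n <- spec$cells_per_dose
    donor_ids <- sprintf("%s_d%02d", spec$group_id,
                         rep_len(seq_len(spec$n_donors), n))
    frail <- if (spec$frailty_sd > 0) {
      f <- rlnorm(spec$n_donors, meanlog = -spec$frailty_sd^2 / 2,
                  sdlog = spec$frailty_sd)
      f[rep_len(seq_len(spec$n_donors), n)]
    } else rep(1, n)
    pieces <- lapply(seq_along(spec$doses), function(k) {
      D <- spec$doses[k]
      d <- spec$dispersion[k]
      lam <- Y$C + Y$alpha * D + Y$beta * D^2
      names(lam) <- rownames(Y)
      cols <- lapply(aberration_classes(), function(cl) {
        if (spec$coupling == "paired" && cl == "ace_4tel") return(NULL)
        if (spec$frailty_sd > 0) {
          vapply(frail * lam[[cl]], function(l) rcount(1L, l, d), 0L)
        } else rcount(n, lam[[cl]], d)
      })
      names(cols) <- aberration_classes()
      if (spec$coupling == "paired") {
        cols$ace_4tel <- cols$dic + cols$cring
      }
      cm <- rep(46L, n)
      if (spec$contamination > 0) {
        bad <- runif(n) < spec$contamination
        cm[bad] <- sample(c(44L, 45L, 47L), sum(bad), replace = TRUE)
      }
      cbind(data.frame(donor_id = donor_ids, group_id = spec$group_id,
                       dose_gy = D, centromere_count = cm,
                       stringsAsFactors = FALSE),
            as.data.frame(cols))
    })
    out <- do.call(rbind, pieces)
    rownames(out) <- NULL
    validate_scores(out)
    out
  })
}

#' Simulate per-dose aggregate tallies directly
#'
#' Fast path equivalent (in distribution) to summing
#' [simulate_cohort()] columns: class totals over `n` cells are Poisson
#' with mean `n * lambda`, or negative binomial with matched total
#' variance under overdispersion. Useful for simulation studies where
#' only the aggregates enter the fit.
#'
#' @param spec A [cohort_spec()].
#' @return A tally data frame (the dialect of [read_tally()]).
#' @export
simulate_tally <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$frailty_sd > 0 || spec$contamination > 0) {
    return(tally_scores(simulate_cohort(spec), drop_incomplete = TRUE))
  }
  with_seed(spec$seed, {
    Y <- spec$class_yields
    n <- spec$cells_per_dose
    pieces <- lapply(seq_along(spec$doses), function(k) {
      D <- spec$doses[k]
      d <- spec$dispersion[k]
      lam <- Y$C + Y$alpha * D + Y$beta * D^2
      names(lam) <- rownames(Y)
      tot <- vapply(aberration_classes(), function(cl) {
        if (spec$coupling == "paired" && cl == "ace_4tel") return(0L)
        as.integer(rcount(1L, n * lam[[cl]], d))
      }, 0L)
      if (spec$coupling == "paired") {
        tot[["ace_4tel"]] <- tot[["dic"]] + tot[["cring"]]
      }
      cbind(data.frame(group_id = spec$group_id, dose_gy = D,
                       n_cells = n, stringsAsFactors = FALSE),
            as.data.frame(as.list(tot)))
    })
    out <- do.call(rbind, pieces)
    rownames(out) <- NULL
    validate_tally(out)
    out
  })
}

#' Simulate an unirradiated (background) cohort
#'
#' Convenience wrapper around [simulate_cohort()] for a zero-dose spec:
#' the expected dicentric total is `n_cells * C_dic`, so e.g. an
#' African-preset background of C = 0 can never produce a dicentric.
#'
#' @param spec A [cohort_spec()] whose doses are all 0.
#' @return A per-metaphase score data frame.
#' @export
simulate_background <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (any(spec$doses != 0)) {
    stop("background simulation requires doses = 0", call. = FALSE)
  }
  simulate_cohort(spec)
}

#' Serialize a cohort spec to YAML (and back)
#'
#' @param spec A `"cohort_spec"`.
#' @param path File path.
#' @return `write_cohort_spec()` returns `path` invisibly;
#'   `read_cohort_spec()` returns the reconstructed `"cohort_spec"`.
#' @export
write_cohort_spec <- function(spec, path) {
  stopifnot(inherits(spec, "cohort_spec"))
  obj <- unclass(spec)
  obj$class_yields <- lapply(as.list(as.data.frame(t(spec$class_yields))),
                             function(v) setNames(as.list(v),
                                                  c("C", "alpha", "beta")))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  obj <- yaml::read_yaml(path)
  cy <- empty_yields()
  for (cl in names(obj$class_yields)) {
    cy[cl, ] <- unlist(obj$class_yields[[cl]])[c("C", "alpha", "beta")]
  }
  cohort_spec(group_id = obj$group_id, doses = obj$doses,
              cells_per_dose = obj$cells_per_dose, class_yields = cy,
              dispersion = obj$dispersion, seed = obj$seed,
              coupling = obj$coupling, contamination = obj$contamination,
              n_donors = obj$n_donors, frailty_sd = obj$frailty_sd)
}
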