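# JSON export/import of curves, dose estimates and comparison results,
# with light structural validation against the schemas shipped under
# inst/schemas/.

curve_to_list <- function(curve) {
  cf <- coef(curve)
  se <- sqrt(diag(vcov(curve)))
  list(endpoint = curve$endpoint,
       C = unname(cf[["C"]]), alpha = unname(cf[["alpha"]]),
       beta = unname(cf[["beta"]]),
       se_C = unname(se[["C"]]), se_alpha = unname(se[["alpha"]]),
       se_beta = unname(se[["beta"]]),
       vcov = as.vector(t(vcov(curve))),
       dispersion_scale = curve$dispersion,
       alpha_beta_ratio = if (cf[["beta"]] > 0)
         unname(cf[["alpha"]] / cf[["beta"]]) else NA)
}

#' Write and read curve JSON
#'
#' The curve JSON carries the endpoint, coefficients, standard errors,
#' the full 3x3 variance-covariance matrix (row-major, 9 values), the
#' dispersion scale, and the alpha/beta ratio. Floats are written at 6
#' significant digits, so identical curves give byte-identical files.
#'
#' @param curve An `"lq_curve"`/`"lq_fit"`.
#' @param path File path.
#' @return `write_curve_json()` returns `path` invisibly;
#'   `read_curve_json()` returns an `"lq_curve"`.
#' @export
write_curve_json <- function(curve, path) {
  obj <- curve_to_list(curve)
  obj <- rapply(obj, function(v) if (is.numeric(v)) signif(v, 6) else v,
                how = "replace")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_curve_json
#' @export
read_curve_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_against_schema(obj, "curve")
  cv <- lq_curve(alpha = obj$alpha, beta = obj$beta, C = obj$C,
                 endpoint = obj$endpoint,
                 dispersion = obj$dispersion_scale)
  cv$vcov <- matrix(obj$vcov, 3L, 3L, byrow = TRUE,
                    dimnames = dimnames(cv$vcov))
  cv
}

#' JSON form of a dose estimate or comparison result
#'
#' @param x A `"dose_estimate"` or `"comparison_result"`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(x, path) {
  obj <- unclass(x)
  obj$detail <- NULL
  obj <- rapply(obj, function(v) if (is.numeric(v)) signif(v, 6) else v,
                how = "replace")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Validate a parsed JSON object against a shipped schema
#'
#' Structural validation: every property the schema marks required must
#' be present with the declared primitive type. (Deliberately a small
#' checker, not a full JSON-Schema engine.)
#'
#' @param obj A list as returned by [jsonlite::read_json()].
#' @param schema Schema name: `"curve"`, `"dose_estimate"` or
#'   `"comparison"`, or a path to a schema file.
#' @return `TRUE` invisibly, or an error naming the offending field.
#' @export
validate_against_schema <- function(obj, schema) {
  path <- if (file.exists(schema)) schema else
    system.file("schemas", paste0(schema, ".json"), package = "cytodose")
  if (!nzchar(path) || !file.exists(path)) {
    stop("unknown schema: ", schema, call. = FALSE)
  }
  sch <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (field in sch$required) {
    if (is.null(obj[[field]])) {
      stop("missing required field '", field, "'", call. = FALSE)
    }
    want <- sch$properties[[field]]$type
    v <- obj[[field]]
    ok <- switch(want,
                 number = is.numeric(v) || is.null(v),
                 integer = is.numeric(v) && all(v == round(v)),
                 string = is.character(v),
                 boolean = is.logical(v),
                 array = is.vector(v) || is.list(v),
                 TRUE)
    if (!ok) {
      stop(sprintf("field '%s' should be of type %s", field, want),
           call. = FALSE)
    }
    n_want <- sch$properties[[field]]$minItems
    if (!is.null(n_want) && length(v) < n_want) {
      stop(sprintf("field '%s' needs at least %d values", field, n_want),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}
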