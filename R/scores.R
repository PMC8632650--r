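# Score-table ingestion and validation.
#
# Two CSV/TSV dialects are supported:
#   per-metaphase: donor_id, group_id, dose_gy, centromere_count,
#                  dic, cring, aring, ace_4tel, ace_2tel, ace_0tel, teldel
#   aggregated:    group_id, dose_gy, n_cells,
#                  dic, cring, aring, ace_4tel, ace_2tel, ace_0tel, teldel

#' Aberration class column names
#'
#' The seven scored aberration classes, in canonical column order:
#' dicentrics (`dic`), centric rings (`cring`), acentric rings (`aring`),
#' acentric fragments with four telomere signals (`ace_4tel`), with two
#' (`ace_2tel`, terminal deletions), with none (`ace_0tel`, interstitial
#' deletions), and telomere deletions (`teldel`).
#'
#' @return Character vector of length 7.
#' @export
aberration_classes <- function() {
  c("dic", "cring", "aring", "ace_4tel", "ace_2tel", "ace_0tel", "teldel")
}

score_header <- function() {
  c("donor_id", "group_id", "dose_gy", "centromere_count",
    aberration_classes())
}

tally_header <- function() {
  c("group_id", "dose_gy", "n_cells", aberration_classes())
}

check_counts <- function(df, cols, what) {
  for (cl in cols) {
    v <- df[[cl]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0) || any(v != round(v))) {
      stop(sprintf("column '%s' of %s must hold non-negative integers",
                   cl, what), call. = FALSE)
    }
  }
  invisible(df)
}

#' Validate a per-metaphase score table
#'
#' Checks that `scores` has the per-metaphase columns, that all aberration
#' and centromere counts are non-negative integers, and that doses are
#' non-negative.
#'
#' @param scores A data frame, one row per scored metaphase.
#' @return `scores`, invisibly, if valid; otherwise an error.
#' @export
validate_scores <- function(scores) {
  miss <- setdiff(score_header(), names(scores))
  if (length(miss)) {
    stop("score table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(scores) == 0L) return(invisible(scores))
  if (!is.numeric(scores$dose_gy) || anyNA(scores$dose_gy) ||
      any(scores$dose_gy < 0)) {
    stop("dose_gy must be non-negative and non-missing", call. = FALSE)
  }
  check_counts(scores, c("centromere_count", aberration_classes()),
               "the score table")
  invisible(scores)
}

#' Validate an aggregated tally table
#'
#' @param tally A data frame, one row per (group, dose) aggregate.
#' @return `tally`, invisibly, if valid; otherwise an error.
#' @export
validate_tally <- function(tally) {
  miss <- setdiff(tally_header(), names(tally))
  if (length(miss)) {
    stop("tally table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(tally) == 0L) return(invisible(tally))
  if (!is.numeric(tally$dose_gy) || anyNA(tally$dose_gy) ||
      any(tally$dose_gy < 0)) {
    stop("dose_gy must be non-negative and non-missing", call. = FALSE)
  }
  check_counts(tally, c("n_cells", aberration_classes()), "the tally table")
  if (any(tally$n_cells < 1)) {
    stop("every tally row must have n_cells >= 1", call. = FALSE)
  }
  invisible(tally)
}

detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

#' Read a score or tally table from CSV/TSV
#'
#' `read_scores()` reads the per-metaphase dialect, `read_tally()` the
#' aggregated one. `read_score_table()` auto-detects the dialect from the
#' header. The field separator (comma or tab) is detected from the first
#' line.
#'
#' @param path Path to a CSV or TSV file.
#' @return A validated data frame; for `read_score_table()` the attribute
#'   `"dialect"` is `"scores"` or `"tally"`.
#' @export
read_scores <- function(path) {
  df <- read.csv(path, sep = detect_sep(path), stringsAsFactors = FALSE)
  validate_scores(df)
  df
}

#' @rdname read_scores
#' @export
read_tally <- function(path) {
  df <- read.csv(path, sep = detect_sep(path), stringsAsFactors = FALSE)
  validate_tally(df)
  df
}

#' @rdname read_scores
#' @export
read_score_table <- function(path) {
  df <- read.csv(path, sep = detect_sep(path), stringsAsFactors = FALSE)
  if ("centromere_count" %in% names(df)) {
    validate_scores(df)
    attr(df, "dialect") <- "scores"
  } else {
    validate_tally(df)
    attr(df, "dialect") <- "tally"
  }
  df
}

#' Keep only analyzable metaphases
#'
#' A metaphase is analyzable when all 46 centromeres are present -- the
#' completeness filter that guarantees no aberration is missed because a
#' chromosome left the spread. Order is preserved; the filter is
#' idempotent.
#'
#' @param scores Per-metaphase score table.
#' @return The rows of `scores` with `centromere_count == 46`.
#' @export
filter_analyzable <- function(scores) {
  validate_scores(scores)
  scores[scores$centromere_count == 46L, , drop = FALSE]
}

#' Aggregate analyzable metaphases into a tally
#'
#' `tally_scores()` aggregates a per-metaphase table by `(group_id,
#' dose_gy)`. All records must be analyzable (46 centromeres); records
#' failing the filter are an error unless `drop_incomplete = TRUE`, in
#' which case they are removed first. `tally_one()` aggregates records
#' that must all belong to a single stated group and dose, rejecting any
#' record that does not match.
#'
#' @param scores Per-metaphase score table.
#' @param drop_incomplete Drop non-analyzable records instead of erroring.
#' @return A tally data frame (one row per group x dose) with columns
#'   `group_id`, `dose_gy`, `n_cells` and the seven class aggregates.
#' @export
tally_scores <- function(scores, drop_incomplete = FALSE) {
  validate_scores(scores)
  bad <- scores$centromere_count != 46L
  if (any(bad)) {
    if (drop_incomplete) {
      scores <- scores[!bad, , drop = FALSE]
    } else {
      stop(sprintf(
        "record %d (donor '%s') has %d centromeres; only 46-centromere metaphases are analyzable",
        which(bad)[1L], scores$donor_id[which(bad)[1L]],
        scores$centromere_count[which(bad)[1L]]), call. = FALSE)
    }
  }
  if (nrow(scores) == 0L) stop("no cells to tally", call. = FALSE)
  key <- interaction(scores$group_id, scores$dose_gy, drop = TRUE,
                     lex.order = TRUE)
  pieces <- lapply(split(scores, key), function(part) {
    agg <- vapply(aberration_classes(), function(cl) sum(part[[cl]]), 0)
    cbind(data.frame(group_id = part$group_id[1L],
                     dose_gy = part$dose_gy[1L],
                     n_cells = nrow(part),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(agg)))
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$group_id, out$dose_gy), , drop = FALSE]
  rownames(out) <- NULL
  validate_tally(out)
  out
}

#' @rdname tally_scores
#' @param group_id,dose_gy The single group and dose every record must
#'   carry.
#' @export
tally_one <- function(scores, group_id, dose_gy) {
  validate_scores(scores)
  if (nrow(scores) == 0L) stop("no cells to tally", call. = FALSE)
  off <- which(scores$group_id != group_id | scores$dose_gy != dose_gy)
  if (length(off)) {
    stop(sprintf(
      "record %d (donor '%s', group '%s', dose %g Gy) does not match group '%s' at %g Gy",
      off[1L], scores$donor_id[off[1L]], scores$group_id[off[1L]],
      scores$dose_gy[off[1L]], group_id, dose_gy), call. = FALSE)
  }
  off <- which(scores$centromere_count != 46L)
  if (length(off)) {
    stop(sprintf("record %d (donor '%s') is not analyzable (%d centromeres)",
                 off[1L], scores$donor_id[off[1L]],
                 scores$centromere_count[off[1L]]), call. = FALSE)
  }
  tally_scores(scores)
}

#' Write a score or tally table as CSV
#'
#' Numeric columns are written at 6 significant digits so identical inputs
#' yield byte-identical files.
#'
#' @param x Data frame to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_csv <- function(x, path) {
  out <- x
  for (cl in names(out)) {
    if (is.numeric(out[[cl]]) && any(out[[cl]] != round(out[[cl]]))) {
      out[[cl]] <- signif(out[[cl]], 6L)
    }
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
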