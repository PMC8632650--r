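# DSB accounting: fixed per-class weights mapping scored aberrations to
# the number of unrepaired/misrepaired double-strand breaks.
#
# Weights: a dicentric or centric ring together with its accompanying
# 4-telomere fragment is the product of one misrepaired fusion = 2 DSB;
# a terminal deletion (2-telomere fragment) = 1 DSB; an interstitial
# deletion (0-telomere fragment) = 2 DSB; a telomere deletion = 1 DSB.
# 4-telomere fragments in excess of the dic+ring count are scored as a
# fusion without a visible exchange partner = 2 DSB each. Acentric rings
# carry a configurable weight (default 2: ring formation needs two
# breaks).

#' Convert an aberration tally to a DSB breakdown
#'
#' Applies the fixed per-class DSB weights to each row of a tally table.
#' A dicentric or centric ring (with its accompanying 4-telomere
#' fragment) counts 2 DSB; terminal deletions (`ace_2tel`) 1 DSB;
#' interstitial deletions (`ace_0tel`) 2 DSB; telomere deletions 1 DSB;
#' 4-telomere fragments in excess of `dic + cring` count 2 DSB each
#' (a fusion event whose exchange partner was not recovered); acentric
#' rings count `aring_weight` DSB.
#'
#' @param tally Tally data frame (see [tally_scores()]), or a single-cell
#'   tally for per-record accounting.
#' @param aring_weight DSB weight of an acentric ring; default 2.
#' @return A data frame with one row per tally row: the identifying
#'   columns, the per-source DSB components (`dsb_from_dic_and_rings`,
#'   `dsb_from_terminal_deletions`, `dsb_from_interstitial_deletions`,
#'   `dsb_from_tel_deletions`, `dsb_from_excess_4tel_fragments`,
#'   `dsb_from_acentric_rings`) and their sum `total_dsb`.
#' @examples
#' t1 <- data.frame(group_id = "g", dose_gy = 2, n_cells = 100,
#'                  dic = 2, cring = 1, aring = 0, ace_4tel = 3,
#'                  ace_2tel = 3, ace_0tel = 1, teldel = 2)
#' count_dsb(t1)$total_dsb  # 13
#' @export
count_dsb <- function(tally, aring_weight = 2) {
  validate_tally(tally)
  if (!is.numeric(aring_weight) || length(aring_weight) != 1L ||
      aring_weight < 0) {
    stop("aring_weight must be a single non-negative number", call. = FALSE)
  }
  fusion <- tally$dic + tally$cring
  out <- data.frame(
    group_id = tally$group_id,
    dose_gy = tally$dose_gy,
    n_cells = tally$n_cells,
    dsb_from_dic_and_rings = 2 * fusion,
    dsb_from_terminal_deletions = tally$ace_2tel,
    dsb_from_interstitial_deletions = 2 * tally$ace_0tel,
    dsb_from_tel_deletions = tally$teldel,
    dsb_from_excess_4tel_fragments = 2 * pmax(0, tally$ace_4tel - fusion),
    dsb_from_acentric_rings = aring_weight * tally$aring,
    stringsAsFactors = FALSE)
  out$total_dsb <- out$dsb_from_dic_and_rings +
    out$dsb_from_terminal_deletions +
    out$dsb_from_interstitial_deletions +
    out$dsb_from_tel_deletions +
    out$dsb_from_excess_4tel_fragments +
    out$dsb_from_acentric_rings
  out
}

#' F-ratio: centric rings per dicentric
#'
#' The ratio of centric rings to dicentric chromosomes, a scoring
#' consistency check: in healthy European donors it sits near 0.05
#' (about one ring per twenty dicentrics). Undefined when no dicentrics
#' were scored, in which case `NA` is returned with a warning rather
#' than a number.
#'
#' @param tally Tally data frame; rows are combined before the ratio is
#'   taken.
#' @return A single number, `cring / dic`, or `NA_real_` if `dic == 0`.
#' @export
f_ratio <- function(tally) {
  validate_tally(tally)
  dic <- sum(tally$dic)
  if (dic == 0) {
    warning("F-ratio undefined: no dicentrics scored", call. = FALSE)
    return(NA_real_)
  }
  sum(tally$cring) / dic
}
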