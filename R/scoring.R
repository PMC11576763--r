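# Morbidscore: one point per supporting source, panel inclusion at >= 1.

#' Compute the Morbidscore
#'
#' Each of the six sources awards a single point when its inclusion
#' criterion is met, however many qualifying records it holds; the
#' Morbidscore is the number of supporting sources, 0-6. Scores are always
#' recomputed from the met flags, never stored independently.
#'
#' @param evidence Evidence tibble (e.g. from [collect_evidence()]) with
#'   the six `<source>_met` logical columns.
#' @return Integer vector of scores, one per row, each in 0..6.
#' @export
#' @examples
#' ev <- tibble::tibble(
#'   omim_met = TRUE, clinvar_met = TRUE, hgmd_met = FALSE,
#'   panelapp_met = FALSE, sysndd_met = FALSE, gencc_met = FALSE
#' )
#' compute_morbidscore(ev) # 2
compute_morbidscore <- function(evidence) {
  missing <- setdiff(met_cols(), names(evidence))
  if (length(missing) > 0) {
    abort(
      paste0("evidence is missing slot(s): ", paste(missing, collapse = ", ")),
      class = "mg_integrity_error"
    )
  }
  flags <- as.matrix(evidence[met_cols()])
  if (nrow(flags) > 0 && (anyNA(flags) || !is.logical(flags))) {
    abort("met flags must be non-missing logicals", class = "mg_integrity_error")
  }
  as.integer(rowSums(flags))
}

#' Panel inclusion rule
#'
#' A gene enters the panel when at least one source criterion is
#' fulfilled, i.e. Morbidscore >= 1. Genes supported by a single source
#' are deliberately kept (limited-evidence genes filterable downstream).
#'
#' @param score Integer vector of Morbidscores in 0..6.
#' @return Logical vector.
#' @export
include_gene <- function(score) {
  if (length(score) > 0 &&
    (anyNA(score) || any(score < 0) || any(score > 6) || any(score != trunc(score)))) {
    abort("score must be integers in 0..6", class = "mg_argument_error")
  }
  score >= 1
}

#' Filter panel rows by minimum Morbidscore
#'
#' User-side stringency filter: keep rows with `morbidscore >= k`,
#' preserving order. `k = 0` is the identity; `k = 7` (one above the
#' maximum) yields an empty panel.
#'
#' @param rows Panel row tibble with a `morbidscore` column.
#' @param k Minimum score, 0..7.
#' @return The filtered tibble.
#' @export
filter_by_min_score <- function(rows, k) {
  if (length(k) != 1 || is.na(k) || k < 0 || k > 7 || k != trunc(k)) {
    abort("k must be a single integer in 0..7", class = "mg_argument_error")
  }
  rows[rows$morbidscore >= k, , drop = FALSE]
}
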