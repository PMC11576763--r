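# Panel summary statistics: score distribution, exclusive (UpSet-style)
# source intersections, PanelApp instance exclusivity, version trend.

#' Morbidscore distribution of a panel
#'
#' @param p A `panel_version`.
#' @return A list of class `score_histogram`: `counts` (named integer
#'   vector over scores 1..6) and `total` (panel size; always the sum of
#'   the counts).
#' @export
score_distribution <- function(p) {
  validate_panel(p)
  counts <- vapply(1:6, function(s) sum(p$rows$morbidscore == s), 0L)
  names(counts) <- as.character(1:6)
  structure(list(counts = counts, total = nrow(p$rows)), class = "score_histogram")
}

#' Exclusive source intersections (UpSet semantics)
#'
#' Assigns each panel gene to exactly one combination: the exact set of
#' sources whose criterion it meets. Counts are therefore exclusive and
#' sum to the panel size; the per-source totals (`singles`) are the
#' marginal sums over all combinations containing that source, i.e. the
#' grey bars of an UpSet plot next to its blue intersection bars.
#'
#' @param p A `panel_version`.
#' @return A list of class `intersection_table`: `rows` (tibble
#'   `combination`, `count`, sorted by count descending then combination)
#'   and `singles` (named integer vector per source).
#' @export
exclusive_intersections <- function(p) {
  validate_panel(p)
  rows <- p$rows
  if (nrow(rows) == 0) {
    return(structure(
      list(
        rows = tibble::tibble(combination = character(), count = integer()),
        singles = setNames(integer(length(MG_SOURCES)), MG_SOURCES)
      ),
      class = "intersection_table"
    ))
  }
  flags <- as.matrix(rows[MG_SOURCES])
  combo <- apply(flags, 1, function(f) paste(MG_SOURCES[f], collapse = "+"))
  tab <- table(combo)
  out <- tibble::tibble(
    combination = names(tab),
    count = as.integer(tab)
  )
  out <- out[order(-out$count, out$combination, method = "radix"), , drop = FALSE]
  singles <- setNames(as.integer(colSums(flags)), MG_SOURCES)
  structure(list(rows = out, singles = singles), class = "intersection_table")
}

#' Green-gene exclusivity between the two PanelApp instances
#'
#' Partitions the green genes (confidence level >= `min_level`) of the two
#' PanelApp instances into those green in both, only in Genomics England,
#' and only in Australia. Gene identity is the harmonized accession.
#'
#' @param entries PanelApp entry tibble (both instances) carrying an
#'   `hgnc_id` column, e.g. panel entries joined against
#'   [resolve_symbols()] output.
#' @param min_level Green threshold (default 3).
#' @return List with character-vector elements `shared`, `ge_only`,
#'   `aus_only`; the three sets partition the green-gene union.
#' @export
exclusive_to_instance <- function(entries, min_level = 3L) {
  green <- entries[entries$confidence_level >= min_level, , drop = FALSE]
  ge <- unique(green$hgnc_id[green$instance == "GenomicsEngland"])
  aus <- unique(green$hgnc_id[green$instance == "Australia"])
  list(
    shared = sort(intersect(ge, aus)),
    ge_only = sort(setdiff(ge, aus)),
    aus_only = sort(setdiff(aus, ge))
  )
}

#' Panel size trend over versions
#'
#' @param panels List of `panel_version` objects with unique labels.
#' @return Tibble with columns `label` and `size`, sorted chronologically
#'   by the label's (year, month).
#' @export
version_trend <- function(panels) {
  labels <- vapply(panels, function(p) p$label, "")
  if (anyDuplicated(labels)) {
    abort("duplicate panel labels", class = "mg_argument_error")
  }
  sizes <- vapply(panels, function(p) nrow(p$rows), 0L)
  ord <- order(labels, method = "radix") # v<YYYY>_<MM> sorts chronologically
  tibble::tibble(label = labels[ord], size = sizes[ord])
}

#' Write the summary statistics of a panel as TSV tables
#'
#' Emits `score_distribution.tsv` (score, count), `intersections.tsv`
#' (combination, count) and, when several panels are given,
#' `version_trend.tsv` (label, size).
#'
#' @param panels A `panel_version` or list of them (the last one is used
#'   for the distribution and intersections).
#' @param out_dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_panel_stats <- function(panels, out_dir) {
  if (inherits(panels, "panel_version")) panels <- list(panels)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- panels[[length(panels)]]
  hist <- score_distribution(p)
  inter <- exclusive_intersections(p)
  paths <- c(
    mg_write_tsv(
      tibble::tibble(score = names(hist$counts), count = hist$counts),
      file.path(out_dir, "score_distribution.tsv")
    ),
    mg_write_tsv(inter$rows, file.path(out_dir, "intersections.tsv"))
  )
  if (length(panels) > 1) {
    paths <- c(paths, mg_write_tsv(
      version_trend(panels),
      file.path(out_dir, "version_trend.tsv")
    ))
  }
  invisible(paths)
}
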