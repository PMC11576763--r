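# Versioned panel assembly, serialization (TSV + JSON sidecar) and diffs.
#
# A panel is a monthly labelled build (v<YYYY>_<MM>): one row per included
# gene carrying the Morbidscore, the six per-source flags and details.
# Output is byte-identical for identical inputs: fixed column order,
# C-locale sort by symbol (hgnc_id tiebreak), "\n" line endings, no
# quoting, tab-free fields.

panel_cols <- function() {
  c("hgnc_id", "symbol", "morbidscore", MG_SOURCES, paste0(MG_SOURCES, "_detail"))
}

new_panel_version <- function(label, build_date, source_meta, rows) {
  structure(
    list(
      label = label,
      build_date = as.Date(build_date),
      source_meta = source_meta,
      rows = rows
    ),
    class = "panel_version"
  )
}

validate_panel <- function(p) {
  if (!grepl(MG_LABEL_RE, p$label)) {
    abort(paste0("invalid version label: ", p$label), class = "mg_integrity_error")
  }
  rows <- p$rows
  missing <- setdiff(panel_cols(), names(rows))
  if (length(missing) > 0) {
    abort(paste0("panel rows missing column(s): ", paste(missing, collapse = ", ")),
      class = "mg_integrity_error"
    )
  }
  if (anyDuplicated(rows$hgnc_id)) {
    abort("duplicate hgnc_id in panel rows", class = "mg_integrity_error")
  }
  if (nrow(rows) > 0) {
    flags <- as.matrix(rows[MG_SOURCES])
    if (!identical(as.integer(rowSums(flags)), as.integer(rows$morbidscore))) {
      abort("morbidscore does not equal the number of met flags",
        class = "mg_integrity_error"
      )
    }
    if (any(rows$morbidscore < 1)) {
      abort("panel rows must have morbidscore >= 1", class = "mg_integrity_error")
    }
    ord <- order(rows$symbol, rows$hgnc_id, method = "radix")
    if (!identical(ord, seq_len(nrow(rows)))) {
      abort("panel rows must be sorted by symbol (hgnc_id tiebreak)",
        class = "mg_integrity_error"
      )
    }
  }
  invisible(p)
}

#' @export
print.panel_version <- function(x, ...) {
  cat(
    "<panel_version> ", x$label, " (", format(x$build_date), "): ",
    nrow(x$rows), " genes\n",
    sep = ""
  )
  invisible(x)
}

#' Build a versioned panel from harmonized evidence
#'
#' Scores every gene, keeps those with Morbidscore >= 1, and sorts rows by
#' symbol (hgnc_id tiebreak, C locale). The build is deterministic for
#' identical inputs.
#'
#' @param evidence Evidence tibble from [collect_evidence()] (its
#'   `$evidence` element), one row per gene with unique `hgnc_id`.
#' @param label Version label matching `v<YYYY>_<MM>`, e.g. `"v2024_10"`.
#' @param source_meta Optional per-source snapshot descriptors (stored in
#'   the JSON sidecar).
#' @param build_date Build date (default today).
#' @return A `panel_version` object.
#' @export
build_panel <- function(evidence, label, source_meta = list(),
                        build_date = Sys.Date()) {
  if (!grepl(MG_LABEL_RE, label)) {
    abort(paste0("invalid version label: ", label), class = "mg_argument_error")
  }
  if (anyDuplicated(evidence$hgnc_id)) {
    abort("duplicate hgnc_id in evidence", class = "mg_integrity_error")
  }
  score <- compute_morbidscore(evidence)
  keep <- include_gene(score)
  rows <- tibble::tibble(
    hgnc_id = evidence$hgnc_id[keep],
    symbol = evidence$symbol[keep],
    morbidscore = score[keep]
  )
  for (src in MG_SOURCES) rows[[src]] <- evidence[[paste0(src, "_met")]][keep]
  for (src in MG_SOURCES) {
    rows[[paste0(src, "_detail")]] <- evidence[[paste0(src, "_detail")]][keep]
  }
  rows <- rows[order(rows$symbol, rows$hgnc_id, method = "radix"), , drop = FALSE]
  p <- new_panel_version(label, build_date, source_meta, rows)
  validate_panel(p)
}

#' Write a panel to disk
#'
#' Writes `<label>.tsv` (flags as TRUE/FALSE strings, no quoting, LF line
#' endings) and `<label>.meta.json` (label, build date, source metadata).
#' `read_panel(write_panel(p))` returns `p` on all fields.
#'
#' @param p A `panel_version`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the path of the TSV file.
#' @export
write_panel <- function(p, out_dir) {
  validate_panel(p)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- file.path(out_dir, paste0(p$label, ".tsv"))
  df <- p$rows[panel_cols()]
  for (src in MG_SOURCES) df[[src]] <- ifelse(df[[src]], "TRUE", "FALSE")
  df$morbidscore <- as.character(df$morbidscore)
  mg_write_tsv(df, tsv)
  meta <- list(
    label = p$label,
    build_date = format(p$build_date, "%Y-%m-%d"),
    source_meta = p$source_meta
  )
  jsonlite::write_json(meta, file.path(out_dir, paste0(p$label, ".meta.json")),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(tsv)
}

#' Read a panel written by [write_panel()]
#'
#' Reads the TSV and its `.meta.json` sidecar and re-validates all panel
#' invariants (unique accessions, label pattern, sort order, score/flag
#' consistency); a file violating them is an integrity error.
#'
#' @param path Path to the panel `.tsv` file.
#' @return A `panel_version`.
#' @export
read_panel <- function(path) {
  df <- mg_read_tsv(path, required_cols = panel_cols())
  rows <- tibble::as_tibble(df[panel_cols()])
  rows$morbidscore <- as.integer(rows$morbidscore)
  for (src in MG_SOURCES) {
    v <- rows[[src]]
    if (!all(v %in% c("TRUE", "FALSE"))) {
      abort(paste0("flag column ", src, " must be TRUE/FALSE"),
        class = "mg_integrity_error"
      )
    }
    rows[[src]] <- v == "TRUE"
  }
  meta_path <- sub("\\.tsv$", ".meta.json", path)
  if (!file.exists(meta_path)) {
    abort(paste0("missing panel sidecar: ", meta_path), class = "mg_input_error")
  }
  meta <- jsonlite::fromJSON(meta_path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  p <- new_panel_version(
    label = meta$label,
    build_date = meta$build_date,
    source_meta = meta$source_meta,
    rows = rows
  )
  validate_panel(p)
}

#' Diff two panel versions
#'
#' Genes added and removed between the versions and, for genes present in
#' both, Morbidscore changes. Symmetric in the sense that
#' `diff_panels(a, b)$added` equals `diff_panels(b, a)$removed`.
#'
#' @param a,b `panel_version` objects (the "from" and "to" versions).
#' @return A list of class `panel_diff`: `from_label`, `to_label`, `added`
#'   and `removed` (character vectors of hgnc_id), and `score_changed`
#'   (tibble `hgnc_id`, `old_score`, `new_score`).
#' @export
diff_panels <- function(a, b) {
  validate_panel(a)
  validate_panel(b)
  ids_a <- a$rows$hgnc_id
  ids_b <- b$rows$hgnc_id
  common <- intersect(ids_a, ids_b)
  old <- a$rows$morbidscore[match(common, ids_a)]
  new <- b$rows$morbidscore[match(common, ids_b)]
  changed <- old != new
  structure(
    list(
      from_label = a$label,
      to_label = b$label,
      added = sort(setdiff(ids_b, ids_a)),
      removed = sort(setdiff(ids_a, ids_b)),
      score_changed = tibble::tibble(
        hgnc_id = common[changed],
        old_score = old[changed],
        new_score = new[changed]
      )
    ),
    class = "panel_diff"
  )
}

#' @export
print.panel_diff <- function(x, ...) {
  cat(
    "<panel_diff> ", x$from_label, " -> ", x$to_label, ": ",
    length(x$added), " added, ", length(x$removed), " removed, ",
    nrow(x$score_changed), " score changes\n",
    sep = ""
  )
  invisible(x)
}
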