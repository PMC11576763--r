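# Evidence assembly: parse all six sources, harmonize symbols, apply each
# criterion per gene, and lay the verdicts out as one wide row per gene.

met_cols <- function() paste0(MG_SOURCES, "_met")

# Apply one source's criterion per harmonized gene.
# records must carry a gene_symbol column; rows whose symbol does not
# resolve are dropped and tallied (design: evidence must land on a stable
# accession, silent misattribution is worse than a logged drop).
criterion_by_gene <- function(records, source, table, criterion_fn) {
  empty <- tibble::tibble(
    hgnc_id = character(), met = logical(), count = integer(), detail = character()
  )
  if (is.null(records) || nrow(records) == 0) {
    return(list(evidence = empty, unmapped = character(0), n_unmapped_records = 0L))
  }
  res <- resolve_symbols(records$gene_symbol, table)
  # identity always comes from the resolver, never from a source's own
  # hgnc_id column (GenCC carries one; it may be stale or absent)
  records <- records[setdiff(names(records), c("hgnc_id", "current_symbol"))]
  joined <- dplyr::left_join(records, res[c("query", "hgnc_id", "current_symbol")],
    by = c(gene_symbol = "query")
  )
  unmapped_rows <- is.na(joined$hgnc_id)
  unmapped_syms <- sort(unique(joined$gene_symbol[unmapped_rows]))
  joined <- joined[!unmapped_rows, , drop = FALSE]
  ev <- if (nrow(joined) == 0) {
    empty
  } else {
    # criterion functions require one symbol per call; records for the same
    # gene under different symbols (aliases) are re-labelled to the current
    # approved symbol before grouping
    joined$gene_symbol <- joined$current_symbol
    parts <- split(joined, joined$hgnc_id)
    dplyr::bind_rows(lapply(names(parts), function(id) {
      out <- criterion_fn(parts[[id]])
      out$hgnc_id <- id
      out
    }))[c("hgnc_id", "met", "count", "detail")]
  }
  list(
    evidence = ev,
    unmapped = unmapped_syms,
    n_unmapped_records = sum(unmapped_rows)
  )
}

#' Collect harmonized per-gene evidence from all six sources
#'
#' Parses the seven snapshot files (symbol table plus six sources, PanelApp
#' as two instance directories), resolves every symbol against the HGNC
#' table, applies each source's inclusion criterion per gene, and returns
#' one wide evidence row per gene with exactly six verdict slots. Records
#' whose symbol cannot be resolved are excluded from scoring and tallied
#' per source.
#'
#' @param paths Named list with elements `hgnc`, `omim`, `clinvar`, `hgmd`,
#'   `panelapp_ge`, `panelapp_aus`, `gencc`, `sysndd` (the PanelApp entries
#'   are directories, the rest files).
#' @param config Thresholds from [build_config()].
#' @return A list with:
#'   \describe{
#'     \item{evidence}{tibble, one row per gene: `hgnc_id`, `symbol`, then
#'       `<source>_met`, `<source>_count`, `<source>_detail` for each of
#'       omim, clinvar, hgmd, panelapp, sysndd, gencc.}
#'     \item{unmapped}{tibble of per-source unmapped-record tallies.}
#'     \item{source_meta}{per-source file name, record count and checksum.}
#'   }
#' @export
collect_evidence <- function(paths, config = build_config()) {
  needed <- c(
    "hgnc", "omim", "clinvar", "hgmd", "panelapp_ge", "panelapp_aus",
    "gencc", "sysndd"
  )
  missing <- setdiff(needed, names(paths))
  if (length(missing) > 0) {
    abort(paste0("paths is missing: ", paste(missing, collapse = ", ")),
      class = "mg_argument_error"
    )
  }
  table <- load_symbol_table(paths$hgnc)

  omim <- parse_omim(paths$omim)
  clinvar <- parse_clinvar(paths$clinvar)
  hgmd <- parse_hgmd(paths$hgmd)
  panelapp <- dplyr::bind_rows(
    parse_panelapp(paths$panelapp_ge, "GenomicsEngland"),
    parse_panelapp(paths$panelapp_aus, "Australia")
  )
  gencc <- parse_gencc(paths$gencc)
  sysndd <- parse_sysndd(paths$sysndd)

  runs <- list(
    omim = criterion_by_gene(
      omim, "omim", table,
      function(r) omim_criterion(r, mapping_keys = config$omim_mapping_keys)
    ),
    clinvar = criterion_by_gene(
      clinvar, "clinvar", table,
      function(r) clinvar_criterion(r, min_count = config$clinvar_min)
    ),
    hgmd = criterion_by_gene(
      hgmd, "hgmd", table,
      function(r) hgmd_criterion(r, min_count = config$hgmd_min, classes = config$hgmd_classes)
    ),
    panelapp = criterion_by_gene(
      panelapp, "panelapp", table,
      function(r) panelapp_criterion(r, min_level = config$panelapp_min_level)
    ),
    sysndd = criterion_by_gene(sysndd, "sysndd", table, sysndd_criterion),
    gencc = criterion_by_gene(gencc, "gencc", table, gencc_criterion)
  )

  ids <- sort(unique(unlist(lapply(runs, function(r) r$evidence$hgnc_id))))
  evidence <- tibble::tibble(
    hgnc_id = ids,
    symbol = unname(table$symbol_lut[ids])
  )
  for (src in MG_SOURCES) {
    ev <- runs[[src]]$evidence
    idx <- match(evidence$hgnc_id, ev$hgnc_id)
    evidence[[paste0(src, "_met")]] <- !is.na(idx) & ev$met[idx]
    evidence[[paste0(src, "_count")]] <- ifelse(is.na(idx), 0L, ev$count[idx])
    evidence[[paste0(src, "_detail")]] <- ifelse(is.na(idx), "", ev$detail[idx])
  }

  unmapped <- dplyr::bind_rows(lapply(MG_SOURCES, function(src) {
    tibble::tibble(
      source = src,
      n_unmapped_records = runs[[src]]$n_unmapped_records,
      unmapped_symbols = paste(runs[[src]]$unmapped, collapse = "|")
    )
  }))

  file_meta <- function(p) {
    if (dir.exists(p)) {
      files <- sort(list.files(p, pattern = "\\.json$", full.names = TRUE))
      list(
        file = basename(p),
        n_records = length(files),
        checksum = unname(tools::md5sum(files)[1]) %||% NA_character_
      )
    } else {
      list(
        file = basename(p),
        n_records = length(readLines(p, warn = FALSE)) - 1L,
        checksum = unname(tools::md5sum(p))
      )
    }
  }
  source_meta <- lapply(
    paths[c("hgnc", "omim", "clinvar", "hgmd", "panelapp_ge", "panelapp_aus", "gencc", "sysndd")],
    file_meta
  )

  list(evidence = evidence, unmapped = unmapped, source_meta = source_meta)
}
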