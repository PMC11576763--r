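# Source snapshot parsers and the six per-source inclusion criteria.
#
# Each criterion reduces one gene's records from one source to a single
# verdict row (source, met, count, detail): the source either supports the
# gene's disease association or it does not, and contributes at most one
# Morbidscore point either way.

source_evidence <- function(source, met, count, detail = "") {
  stopifnot(source %in% MG_SOURCES)
  if (met && count < 1) {
    abort("met evidence requires count >= 1", class = "mg_integrity_error")
  }
  tibble::tibble(
    source = source, met = met, count = as.integer(count), detail = detail
  )
}

no_evidence <- function(source) source_evidence(source, FALSE, 0L)

# ---- OMIM -------------------------------------------------------------

#' Parse an OMIM genemap2-style snapshot
#'
#' Expects a TSV with columns `Gene Symbols`, `MIM Number`, `Phenotypes`.
#' The `Phenotypes` cell holds semicolon-separated entries of the form
#' `"<label>, <phenoMIM> (<mappingKey>)"`; prefix markers `?` (provisional),
#' `{...}` (susceptibility) and `[...]` (nondisease) are kept verbatim in
#' the label. Only the first (approved) symbol of the `Gene Symbols` cell
#' is used; the remainder are aliases of the same gene and would duplicate
#' evidence after harmonization.
#'
#' @param path Path to the TSV file.
#' @return Tibble with one row per (gene, phenotype entry): `gene_symbol`,
#'   `mim_number`, `phenotype_label`, `mapping_key` (integer 1-4 or `NA`
#'   when the mapping-key parenthetical is malformed, with a warning).
#' @export
parse_omim <- function(path) {
  df <- mg_read_tsv(path, required_cols = c("Gene Symbols", "MIM Number", "Phenotypes"))
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    pheno_cell <- df$Phenotypes[i]
    if (!nzchar(trimws(pheno_cell))) next
    gene <- trimws(strsplit(df$`Gene Symbols`[i], ",", fixed = TRUE)[[1]][1])
    entries <- trimws(strsplit(pheno_cell, ";", fixed = TRUE)[[1]])
    entries <- entries[nzchar(entries)]
    m <- regmatches(
      entries,
      regexec("^(.*),\\s*([0-9]{4,6})\\s*\\(([1-4])\\)$", entries)
    )
    label <- character(length(entries))
    key <- integer(length(entries))
    for (j in seq_along(entries)) {
      if (length(m[[j]]) == 4) {
        label[j] <- trimws(m[[j]][2])
        key[j] <- as.integer(m[[j]][4])
      } else {
        # no well-formed "(<key>)" tail: keep the association, flag the key
        label[j] <- entries[j]
        key[j] <- NA_integer_
        warn(paste0(
          "malformed mapping key in phenotype entry: '", entries[j],
          "' (gene ", gene, ")"
        ))
      }
    }
    out[[i]] <- tibble::tibble(
      gene_symbol = gene,
      mim_number = as.integer(df$`MIM Number`[i]),
      phenotype_label = label,
      mapping_key = key
    )
  }
  dplyr::bind_rows(out)
}

omim_qualifies <- function(label, mapping_key, mapping_keys = c(3L, 4L)) {
  lab <- trimws(label)
  first <- substr(lab, 1, 1)
  !(first %in% c("?", "{", "[")) & !is.na(mapping_key) &
    mapping_key %in% mapping_keys
}

#' OMIM inclusion criterion
#'
#' A gene qualifies when at least one phenotype association is a plain
#' disease entry: no `?` (provisional), `{...}` (susceptibility) or
#' `[...]` (nondisease) marker, and a mapping key in `mapping_keys`
#' (default 3 and 4: molecular basis known / chromosomal).
#'
#' @param associations Tibble from [parse_omim()], all rows for one gene.
#' @param mapping_keys Qualifying mapping keys.
#' @return One-row evidence tibble (`source`, `met`, `count`, `detail`).
#' @export
omim_criterion <- function(associations, mapping_keys = c(3L, 4L)) {
  if (is.null(associations) || nrow(associations) == 0) {
    return(no_evidence("omim"))
  }
  stopifnot(length(unique(associations$gene_symbol)) == 1)
  ok <- omim_qualifies(
    associations$phenotype_label, associations$mapping_key, mapping_keys
  )
  n <- sum(ok)
  source_evidence(
    "omim", n >= 1, n,
    detail = if (n >= 1) associations$phenotype_label[ok][1] else ""
  )
}

# ---- ClinVar ----------------------------------------------------------

#' Parse a ClinVar variant_summary-style snapshot
#'
#' Expects a TSV with columns `VariationID`, `Type`, `GeneSymbol`,
#' `ClinicalSignificance`, `OriginSimple`, `Assembly`. Semicolon-separated
#' multi-gene `GeneSymbol` cells expand to one record per symbol; rows are
#' then deduplicated by (VariationID, gene) keeping the first occurrence,
#' so the per-assembly duplicate rows of a variant_summary table count
#' once. Rows with a non-integer VariationID are skipped with a warning.
#'
#' @param path Path to the TSV file.
#' @return Tibble with columns `variation_id`, `gene_symbol`,
#'   `variant_type`, `clinical_significance`, `origin`, `assembly`.
#' @export
parse_clinvar <- function(path) {
  df <- mg_read_tsv(path, required_cols = c(
    "VariationID", "Type", "GeneSymbol", "ClinicalSignificance",
    "OriginSimple", "Assembly"
  ))
  ids <- suppressWarnings(as.integer(df$VariationID))
  bad <- is.na(ids)
  if (any(bad)) {
    warn(paste0(
      sum(bad), " ClinVar row(s) skipped: non-integer VariationID (",
      paste(head(unique(df$VariationID[bad]), 3), collapse = ", "), ")"
    ))
    df <- df[!bad, , drop = FALSE]
    ids <- ids[!bad]
  }
  out <- tibble::tibble(
    variation_id = ids,
    gene_symbol = df$GeneSymbol,
    variant_type = df$Type,
    clinical_significance = df$ClinicalSignificance,
    origin = df$OriginSimple,
    assembly = df$Assembly
  )
  out <- tidyr::separate_rows(out, "gene_symbol", sep = ";")
  out$gene_symbol <- trimws(out$gene_symbol)
  out <- out[nzchar(out$gene_symbol), , drop = FALSE]
  out[!duplicated(out[c("variation_id", "gene_symbol")]), , drop = FALSE]
}

clinvar_qualifies <- function(significance, variant_type) {
  sig <- tolower(significance)
  grepl("pathogenic", sig, fixed = TRUE) &
    !grepl("conflicting", sig, fixed = TRUE) &
    !(tolower(variant_type) %in% c("copy number gain", "copy number loss"))
}

#' ClinVar inclusion criterion
#'
#' A variant qualifies when its clinical significance contains
#' "pathogenic" but not "conflicting" (case-insensitive, so "Pathogenic",
#' "Likely pathogenic" and "Pathogenic/Likely pathogenic" all count) and
#' its type is not a copy number gain/loss. Origin is ignored, so somatic
#' variants count. The gene qualifies at `min_count` (default 4)
#' deduplicated qualifying variants.
#'
#' @param records Tibble from [parse_clinvar()], all rows for one gene.
#' @param min_count Minimum qualifying variants.
#' @return One-row evidence tibble.
#' @export
clinvar_criterion <- function(records, min_count = 4L) {
  if (is.null(records) || nrow(records) == 0) {
    return(no_evidence("clinvar"))
  }
  stopifnot(length(unique(records$gene_symbol)) == 1)
  n <- sum(clinvar_qualifies(records$clinical_significance, records$variant_type))
  source_evidence(
    "clinvar", n >= min_count, n,
    detail = if (n > 0) paste0(n, " (likely) pathogenic variant(s)") else ""
  )
}

# ---- HGMD -------------------------------------------------------------

HGMD_CLASSES <- c("DM", "DM?", "DP", "DFP", "FP", "R")

#' Parse an HGMD-like variant-class snapshot
#'
#' Expects a TSV with columns `gene`, `variant_id`, `variant_class`.
#' Rows with a class outside DM, DM?, DP, DFP, FP, R are skipped with a
#' warning.
#'
#' @param path Path to the TSV file.
#' @return Tibble with columns `gene_symbol`, `variant_id`, `variant_class`.
#' @export
parse_hgmd <- function(path) {
  df <- mg_read_tsv(path, required_cols = c("gene", "variant_id", "variant_class"))
  known <- df$variant_class %in% HGMD_CLASSES
  if (any(!known)) {
    warn(paste0(
      sum(!known), " HGMD row(s) skipped: unknown variant class (",
      paste(head(unique(df$variant_class[!known]), 3), collapse = ", "), ")"
    ))
  }
  tibble::tibble(
    gene_symbol = df$gene[known],
    variant_id = df$variant_id[known],
    variant_class = df$variant_class[known]
  )
}

#' HGMD inclusion criterion
#'
#' Counts variants whose class is in `classes` (default `"DM"` only;
#' `c("DM", "DM?")` admits questioned disease-causing mutations too).
#' The gene qualifies at `min_count` (default 4) such variants.
#'
#' @param records Tibble from [parse_hgmd()], all rows for one gene.
#' @param min_count Minimum qualifying variants.
#' @param classes Qualifying variant classes.
#' @return One-row evidence tibble.
#' @export
hgmd_criterion <- function(records, min_count = 4L, classes = "DM") {
  if (is.null(records) || nrow(records) == 0) {
    return(no_evidence("hgmd"))
  }
  stopifnot(length(unique(records$gene_symbol)) == 1)
  n <- sum(records$variant_class %in% classes)
  source_evidence(
    "hgmd", n >= min_count, n,
    detail = if (n > 0) paste0(n, " pathogenic variant(s)") else ""
  )
}

# ---- PanelApp ---------------------------------------------------------

#' Parse a directory of PanelApp-export-style JSON panels
#'
#' Each JSON file holds one panel: fields `id`, `name` and `genes`, a list
#' of objects with `entity_name` and `confidence_level` (a numeric
#' string, coerced to integer).
#'
#' @param dir_path Directory of `.json` files.
#' @param instance `"GenomicsEngland"` or `"Australia"`.
#' @return Tibble with one row per (panel, gene): `instance`, `panel_id`,
#'   `panel_name`, `gene_symbol`, `confidence_level`.
#' @export
parse_panelapp <- function(dir_path, instance = c("GenomicsEngland", "Australia")) {
  instance <- match.arg(instance)
  if (!dir.exists(dir_path)) {
    abort(paste0("PanelApp directory not found: ", dir_path), class = "mg_input_error")
  }
  files <- sort(list.files(dir_path, pattern = "\\.json$", full.names = TRUE))
  out <- lapply(files, function(f) {
    panel <- tryCatch(
      jsonlite::fromJSON(f, simplifyVector = FALSE),
      error = function(e) {
        abort(paste0("unparseable PanelApp JSON file: ", f),
          class = "mg_format_error", parent = e
        )
      }
    )
    genes <- panel$genes %||% list()
    if (length(genes) == 0) {
      return(NULL)
    }
    tibble::tibble(
      instance = instance,
      panel_id = as.integer(panel$id),
      panel_name = as.character(panel$name),
      gene_symbol = vapply(genes, function(g) as.character(g$entity_name), ""),
      confidence_level = vapply(
        genes, function(g) as.integer(as.numeric(g$confidence_level)), 0L
      )
    )
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble::tibble(
      instance = character(), panel_id = integer(), panel_name = character(),
      gene_symbol = character(), confidence_level = integer()
    )
  }
  res
}

#' PanelApp inclusion criterion
#'
#' A gene qualifies with a green curation status — confidence level at
#' least `min_level` (default 3) — in at least one panel of either the
#' Genomics England or the Australia instance.
#'
#' @param entries Tibble from [parse_panelapp()] (both instances
#'   concatenated), all rows for one gene.
#' @param min_level Minimum confidence level for green status.
#' @return One-row evidence tibble; `detail` lists the qualifying panels
#'   tagged by instance.
#' @export
panelapp_criterion <- function(entries, min_level = 3L) {
  if (is.null(entries) || nrow(entries) == 0) {
    return(no_evidence("panelapp"))
  }
  stopifnot(length(unique(entries$gene_symbol)) == 1)
  ok <- entries$confidence_level >= min_level
  n <- sum(ok)
  tag <- c(GenomicsEngland = "GE", Australia = "AUS")[entries$instance[ok]]
  source_evidence(
    "panelapp", n >= 1, n,
    detail = if (n >= 1) {
      paste(paste0(tag, ":", entries$panel_name[ok]), collapse = "; ")
    } else {
      ""
    }
  )
}

# ---- GenCC ------------------------------------------------------------

#' Parse a GenCC submissions snapshot
#'
#' Expects a TSV with columns `gene_symbol`, `hgnc_id`, `disease`,
#' `classification`, `submitter`.
#'
#' @param path Path to the TSV file.
#' @return Tibble with one row per submission.
#' @export
parse_gencc <- function(path) {
  df <- mg_read_tsv(path, required_cols = c(
    "gene_symbol", "hgnc_id", "disease", "classification", "submitter"
  ))
  tibble::tibble(
    gene_symbol = df$gene_symbol,
    hgnc_id = ifelse(nzchar(df$hgnc_id), df$hgnc_id, NA_character_),
    disease_label = df$disease,
    classification = df$classification,
    submitter = df$submitter
  )
}

#' GenCC inclusion criterion
#'
#' A submission qualifies when its classification is "Definitive"
#' (case-insensitive exact match); "Strong" and below do not qualify.
#'
#' @param submissions Tibble from [parse_gencc()], all rows for one gene.
#' @return One-row evidence tibble.
#' @export
gencc_criterion <- function(submissions) {
  if (is.null(submissions) || nrow(submissions) == 0) {
    return(no_evidence("gencc"))
  }
  stopifnot(length(unique(submissions$gene_symbol)) == 1)
  ok <- tolower(submissions$classification) == "definitive"
  n <- sum(ok)
  source_evidence(
    "gencc", n >= 1, n,
    detail = if (n >= 1) submissions$disease_label[ok][1] else ""
  )
}

# ---- SysNDD -----------------------------------------------------------

#' Parse a SysNDD entity snapshot
#'
#' Expects a TSV with columns `symbol`, `status`, `disease`.
#'
#' @param path Path to the TSV file.
#' @return Tibble with one row per entity.
#' @export
parse_sysndd <- function(path) {
  df <- mg_read_tsv(path, required_cols = c("symbol", "status", "disease"))
  tibble::tibble(
    gene_symbol = df$symbol,
    status = df$status,
    disease_label = df$disease
  )
}

#' SysNDD inclusion criterion
#'
#' An entity qualifies when its status is "Definitive" or "Definite"
#' (case-insensitive; both spellings occur in the wild).
#'
#' @param entries Tibble from [parse_sysndd()], all rows for one gene.
#' @return One-row evidence tibble.
#' @export
sysndd_criterion <- function(entries) {
  if (is.null(entries) || nrow(entries) == 0) {
    return(no_evidence("sysndd"))
  }
  stopifnot(length(unique(entries$gene_symbol)) == 1)
  ok <- tolower(entries$status) %in% c("definitive", "definite")
  n <- sum(ok)
  source_evidence(
    "sysndd", n >= 1, n,
    detail = if (n >= 1) entries$disease_label[ok][1] else ""
  )
}
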