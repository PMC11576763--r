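# Shared helpers: tiny hand-written snapshots and an independent
# brute-force evidence oracle used to cross-check the adapters.

write_lines_tsv <- function(path, lines) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  path
}

# Minimal three-gene symbol table: AAA (alias AX, prev AOLD), BBB, CCC;
# alias "SHARED" is ambiguous between BBB and CCC; WWW is withdrawn.
tiny_symbol_table <- function(dir = withr::local_tempdir()) {
  path <- file.path(dir, "hgnc.tsv")
  write_lines_tsv(path, c(
    "hgnc_id\tsymbol\tstatus\tprev_symbols\talias_symbols",
    "HGNC:1\tAAA\tapproved\tAOLD\tAX",
    "HGNC:2\tBBB\tapproved\t\tSHARED",
    "HGNC:3\tCCC\tapproved\t\tSHARED|CX",
    "HGNC:9\tWWW\twithdrawn\t\t"
  ))
  load_symbol_table(path)
}

# Independent brute-force re-derivation of every (met, count) verdict from
# the raw snapshot files: plain base-R row filtering, grouping and
# counting, sharing no code with the adapters.
brute_force_verdicts <- function(dir) {
  read_tsv0 <- function(f) {
    utils::read.delim(file.path(dir, f),
      sep = "\t", quote = "", check.names = FALSE,
      colClasses = "character"
    )
  }
  hgnc <- read_tsv0("hgnc.tsv")
  # map any emitted symbol (approved, prev or alias; fixture tables are
  # unambiguous) back to the approved symbol
  sym_map <- new.env()
  for (i in seq_len(nrow(hgnc))) {
    if (hgnc$status[i] != "approved") next
    assign(hgnc$symbol[i], hgnc$symbol[i], envir = sym_map)
    for (col in c("prev_symbols", "alias_symbols")) {
      for (s in strsplit(hgnc[[col]][i], "|", fixed = TRUE)[[1]]) {
        if (nzchar(s)) assign(s, hgnc$symbol[i], envir = sym_map)
      }
    }
  }
  canon <- function(x) {
    vapply(x, function(s) get0(s, envir = sym_map, ifnotfound = NA_character_), "")
  }
  count_by <- function(genes) {
    genes <- genes[!is.na(genes)]
    tab <- table(genes)
    stats::setNames(as.integer(tab), names(tab))
  }

  omim <- read_tsv0("omim.tsv")
  omim_genes <- character(0)
  for (i in seq_len(nrow(omim))) {
    entries <- strsplit(omim$Phenotypes[i], ";", fixed = TRUE)[[1]]
    for (e in trimws(entries)) {
      if (!nzchar(e)) next
      has_key34 <- grepl("\\((3|4)\\)$", e)
      excluded <- grepl("^[?{\\[]", e)
      if (has_key34 && !excluded) {
        omim_genes <- c(omim_genes, trimws(strsplit(omim$`Gene Symbols`[i], ",")[[1]][1]))
      }
    }
  }
  omim_n <- count_by(canon(omim_genes))

  cv <- read_tsv0("clinvar.tsv")
  if (nrow(cv) > 0) {
    cv <- cv[!duplicated(cv[c("VariationID", "GeneSymbol")]), ]
    sig <- tolower(cv$ClinicalSignificance)
    ok <- grepl("pathogenic", sig) & !grepl("conflicting", sig) &
      !(tolower(cv$Type) %in% c("copy number gain", "copy number loss"))
    cv_n <- count_by(canon(cv$GeneSymbol[ok]))
  } else {
    cv_n <- integer(0)
  }

  hg <- read_tsv0("hgmd.tsv")
  hg_n <- count_by(canon(hg$gene[hg$variant_class == "DM"]))

  pa_genes <- character(0)
  for (d in c("panelapp_ge", "panelapp_aus")) {
    for (f in list.files(file.path(dir, d), pattern = "\\.json$", full.names = TRUE)) {
      panel <- jsonlite::fromJSON(f, simplifyVector = FALSE)
      for (g in panel$genes) {
        if (as.integer(g$confidence_level) >= 3) {
          pa_genes <- c(pa_genes, g$entity_name)
        }
      }
    }
  }
  pa_n <- count_by(canon(pa_genes))

  gc <- read_tsv0("gencc.tsv")
  gc_n <- count_by(canon(gc$gene_symbol[tolower(gc$classification) == "definitive"]))

  sn <- read_tsv0("sysndd.tsv")
  sn_n <- count_by(canon(sn$symbol[tolower(sn$status) %in% c("definitive", "definite")]))

  get_n <- function(counts, g) if (g %in% names(counts)) counts[[g]] else 0L
  genes <- hgnc$symbol[hgnc$status == "approved"]
  out <- lapply(genes, function(g) {
    counts <- c(
      omim = get_n(omim_n, g), clinvar = get_n(cv_n, g),
      hgmd = get_n(hg_n, g), panelapp = get_n(pa_n, g),
      sysndd = get_n(sn_n, g), gencc = get_n(gc_n, g)
    )
    met <- c(
      omim = counts[["omim"]] >= 1, clinvar = counts[["clinvar"]] >= 4,
      hgmd = counts[["hgmd"]] >= 4, panelapp = counts[["panelapp"]] >= 1,
      sysndd = counts[["sysndd"]] >= 1, gencc = counts[["gencc"]] >= 1
    )
    list(symbol = g, counts = counts, met = met)
  })
  stats::setNames(out, genes)
}

# Build a panel from a generated universe and return panel + ground truth.
build_universe <- function(spec, label = "v2024_01") {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  gt <- generate_universe(spec, dir)
  built <- build_panel_from_dir(dir, label, build_date = as.Date("2024-01-15"))
  list(dir = dir, gt = gt, panel = built$panel, unmapped = built$unmapped)
}

# Hand-built single-gene record tibbles for criterion unit tests.
cv_rec <- function(n, sig = "Pathogenic", type = "single nucleotide variant",
                   origin = "germline", gene = "AAA", start_id = 1L) {
  tibble::tibble(
    variation_id = start_id + seq_len(n) - 1L, gene_symbol = gene,
    variant_type = type, clinical_significance = sig,
    origin = origin, assembly = "GRCh38"
  )
}

hg_rec <- function(n, class = "DM", gene = "AAA") {
  tibble::tibble(
    gene_symbol = gene, variant_id = sprintf("CM%03d", seq_len(n)),
    variant_class = class
  )
}

pa_entry <- function(level, instance = "GenomicsEngland", gene = "AAA",
                     panel = "Panel X") {
  tibble::tibble(
    instance = instance, panel_id = 1L, panel_name = panel,
    gene_symbol = gene, confidence_level = as.integer(level)
  )
}

# One wide evidence row with the given six met flags (source order).
evidence_row <- function(met, id = "HGNC:1", symbol = "AAA") {
  stopifnot(length(met) == 6)
  ev <- tibble::tibble(hgnc_id = id, symbol = symbol)
  for (i in seq_along(panel_sources())) {
    src <- panel_sources()[i]
    ev[[paste0(src, "_met")]] <- met[i]
    ev[[paste0(src, "_count")]] <- as.integer(met[i])
    ev[[paste0(src, "_detail")]] <- ""
  }
  ev
}

# Panel rows reduced to the oracle-comparable columns.
panel_core <- function(p) {
  as.data.frame(p$rows[c("hgnc_id", "symbol", "morbidscore", panel_sources())])
}
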