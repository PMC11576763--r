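# Synthetic snapshot generator: emits all seven input dialects for a
# planted gene-by-source membership matrix, so the whole pipeline can be
# validated against known ground truth without touching any real
# (licensed, point-in-time) database. Symbols are synthetic (GENE0001...).
#
# The generator is constructive in both directions: a gene planted as a
# member of a source gets records that satisfy that source's criterion; a
# non-member gets only records (including decoys for every exclusion rule)
# that fail it. Same seed, same spec => byte-identical files.

DECOY_CLASSES <- c(
  "omim_provisional", "omim_susceptibility", "omim_nondisease",
  "clinvar_cnv", "clinvar_conflicting", "hgmd_dmq",
  "panelapp_amber_red", "gencc_strong", "sysndd_limited"
)

#' Specify a synthetic snapshot universe
#'
#' @param n_genes Number of genes.
#' @param membership Either a logical `n_genes x 6` matrix with columns
#'   named as [panel_sources()], or a named numeric vector of per-source
#'   inclusion probabilities in `[0, 1]` (recycled defaults shown below).
#'   The defaults mirror the qualitative ordering seen in real panels:
#'   four broad sources dominate, the phenotype-specific SysNDD is the
#'   smallest.
#' @param clinvar_count_range,hgmd_count_range Qualifying-variant counts
#'   for member genes (default 4-8, i.e. at or above the inclusion
#'   threshold of four).
#' @param nonmember_count_range Qualifying-variant counts for non-member
#'   genes (default 0-3, strictly below threshold).
#' @param decoy_rates Named probabilities of emitting excluded-record
#'   decoys per gene, one per exclusion rule: provisional/susceptibility/
#'   nondisease OMIM lines, CNV or conflicting ClinVar lines, DM? HGMD
#'   lines, amber/red PanelApp entries, Strong GenCC lines, Limited SysNDD
#'   lines. A single number applies to all classes.
#' @param alias_rate Fraction of genes emitted under an alias symbol in
#'   one randomly chosen source (exercises harmonization).
#' @param seed Integer seed; fully determines the output bytes.
#' @return A validated list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_genes = 200L,
                         membership = c(
                           omim = 0.60, clinvar = 0.55, hgmd = 0.55,
                           panelapp = 0.60, sysndd = 0.15, gencc = 0.40
                         ),
                         clinvar_count_range = c(4L, 8L),
                         hgmd_count_range = c(4L, 8L),
                         nonmember_count_range = c(0L, 3L),
                         decoy_rates = 0.3,
                         alias_rate = 0.1,
                         seed = 1L) {
  if (length(n_genes) != 1 || is.na(n_genes) || n_genes < 1) {
    abort("n_genes must be a positive integer", class = "mg_argument_error")
  }
  if (is.matrix(membership)) {
    if (!identical(sort(colnames(membership)), sort(MG_SOURCES)) ||
      nrow(membership) != n_genes || !is.logical(membership)) {
      abort("membership matrix must be logical, n_genes x 6, columns named by source",
        class = "mg_argument_error"
      )
    }
    membership <- membership[, MG_SOURCES, drop = FALSE]
  } else {
    if (is.null(names(membership)) || !all(MG_SOURCES %in% names(membership)) ||
      any(membership < 0) || any(membership > 1)) {
      abort("membership probabilities must be named by source and lie in [0, 1]",
        class = "mg_argument_error"
      )
    }
    membership <- membership[MG_SOURCES]
  }
  chk_range <- function(r, what) {
    if (length(r) != 2 || any(r < 0) || r[1] > r[2]) {
      abort(paste0(what, " must be a non-negative (lo, hi) range"),
        class = "mg_argument_error"
      )
    }
  }
  chk_range(clinvar_count_range, "clinvar_count_range")
  chk_range(hgmd_count_range, "hgmd_count_range")
  chk_range(nonmember_count_range, "nonmember_count_range")
  if (clinvar_count_range[1] < 4 || hgmd_count_range[1] < 4) {
    abort("member count ranges must start at the inclusion threshold (4)",
      class = "mg_argument_error"
    )
  }
  if (nonmember_count_range[2] > 3) {
    abort("nonmember count range must stay below the inclusion threshold",
      class = "mg_argument_error"
    )
  }
  if (length(decoy_rates) == 1 && is.null(names(decoy_rates))) {
    decoy_rates <- setNames(rep(decoy_rates, length(DECOY_CLASSES)), DECOY_CLASSES)
  }
  if (!all(DECOY_CLASSES %in% names(decoy_rates)) ||
    any(decoy_rates < 0) || any(decoy_rates > 1)) {
    abort(paste0(
      "decoy_rates must cover all classes with probabilities in [0, 1]: ",
      paste(DECOY_CLASSES, collapse = ", ")
    ), class = "mg_argument_error")
  }
  if (alias_rate < 0 || alias_rate > 1) {
    abort("alias_rate must lie in [0, 1]", class = "mg_argument_error")
  }
  structure(
    list(
      n_genes = as.integer(n_genes),
      membership = membership,
      clinvar_count_range = as.integer(clinvar_count_range),
      hgmd_count_range = as.integer(hgmd_count_range),
      nonmember_count_range = as.integer(nonmember_count_range),
      decoy_rates = decoy_rates[DECOY_CLASSES],
      alias_rate = alias_rate,
      seed = as.integer(seed)
    ),
    class = "fixture_spec"
  )
}

rint <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n) else sample(range[1]:range[2], n, replace = TRUE)
}

#' Generate a synthetic snapshot universe
#'
#' Writes `hgnc.tsv`, `omim.tsv`, `clinvar.tsv`, `hgmd.tsv`,
#' `panelapp_ge/*.json`, `panelapp_aus/*.json`, `gencc.tsv`, `sysndd.tsv`
#' and `manifest.json` under `out_dir`, and returns the planted ground
#' truth. Member genes receive records satisfying the source criterion;
#' non-members receive only sub-threshold records and decoys that every
#' exclusion rule must reject. ClinVar variants are emitted once per
#' assembly (GRCh37 and GRCh38) so the deduplication rule is always
#' exercised.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Output directory (created; must be empty or absent).
#' @return The ground-truth tibble, invisibly also written into the
#'   manifest: per gene `hgnc_id`, `symbol`, the six planted membership
#'   flags, `clinvar_count` / `hgmd_count` (planted qualifying counts),
#'   `alias_source` (which source saw the alias symbol, or `NA`),
#'   `expected_score` and `expected_inclusion`.
#' @export
generate_universe <- function(spec, out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$seed)
  n <- spec$n_genes

  symbol <- sprintf("GENE%04d", seq_len(n))
  hgnc_id <- sprintf("HGNC:%d", 10000L + seq_len(n))
  alias <- paste0(symbol, "ALT")
  prev <- paste0(symbol, "OLD")

  if (is.matrix(spec$membership)) {
    member <- spec$membership
  } else {
    member <- vapply(
      MG_SOURCES,
      function(src) runif(n) < spec$membership[[src]],
      logical(n)
    )
    if (n == 1) member <- matrix(member, nrow = 1, dimnames = list(NULL, MG_SOURCES))
  }

  clinvar_count <- ifelse(
    member[, "clinvar"],
    rint(n, spec$clinvar_count_range),
    rint(n, spec$nonmember_count_range)
  )
  hgmd_count <- ifelse(
    member[, "hgmd"],
    rint(n, spec$hgmd_count_range),
    rint(n, spec$nonmember_count_range)
  )

  decoy <- vapply(
    DECOY_CLASSES,
    function(cl) runif(n) < spec$decoy_rates[[cl]],
    logical(n)
  )
  if (n == 1) decoy <- matrix(decoy, nrow = 1, dimnames = list(NULL, DECOY_CLASSES))

  aliased <- runif(n) < spec$alias_rate
  alias_source <- ifelse(aliased, sample(MG_SOURCES, n, replace = TRUE), NA_character_)
  # the symbol each source sees for each gene
  sym_for <- function(src) ifelse(!is.na(alias_source) & alias_source == src, alias, symbol)

  # ---- hgnc.tsv
  mg_write_tsv(
    tibble::tibble(
      hgnc_id = hgnc_id, symbol = symbol, status = "approved",
      prev_symbols = prev, alias_symbols = alias
    ),
    file.path(out_dir, "hgnc.tsv")
  )

  # ---- omim.tsv
  omim_sym <- sym_for("omim")
  omim_rows <- list()
  for (i in seq_len(n)) {
    entries <- character(0)
    if (member[i, "omim"]) {
      entries <- c(entries, sprintf("Disease %s, %d (3)", symbol[i], 600000L + i))
    }
    if (decoy[i, "omim_provisional"]) {
      entries <- c(entries, sprintf("?Provisional disease %s, %d (3)", symbol[i], 610000L + i))
    }
    if (decoy[i, "omim_susceptibility"]) {
      entries <- c(entries, sprintf("{Susceptibility to disease %s}, %d (3)", symbol[i], 620000L + i))
    }
    if (decoy[i, "omim_nondisease"]) {
      entries <- c(entries, sprintf("[Nondisease trait %s], %d (3)", symbol[i], 630000L + i))
    }
    if (length(entries) > 0) {
      omim_rows[[length(omim_rows) + 1]] <- tibble::tibble(
        `Gene Symbols` = omim_sym[i],
        `MIM Number` = as.character(100000L + i),
        Phenotypes = paste(entries, collapse = "; ")
      )
    }
  }
  mg_write_tsv(
    dplyr::bind_rows(c(omim_rows, list(tibble::tibble(
      `Gene Symbols` = character(), `MIM Number` = character(), Phenotypes = character()
    )))),
    file.path(out_dir, "omim.tsv")
  )

  # ---- clinvar.tsv (each variant on both assemblies: dedup must collapse)
  clinvar_sym <- sym_for("clinvar")
  next_vid <- 1L
  cv_rows <- list()
  add_cv <- function(sym, type, sig, origin) {
    vid <- next_vid
    next_vid <<- next_vid + 1L
    tibble::tibble(
      VariationID = as.character(vid),
      Type = type, GeneSymbol = sym, ClinicalSignificance = sig,
      OriginSimple = origin, Assembly = c("GRCh37", "GRCh38")
    )
  }
  path_sigs <- c("Pathogenic", "Likely pathogenic", "Pathogenic/Likely pathogenic")
  for (i in seq_len(n)) {
    k <- clinvar_count[i]
    if (k > 0) {
      for (j in seq_len(k)) {
        cv_rows[[length(cv_rows) + 1]] <- add_cv(
          clinvar_sym[i], "single nucleotide variant",
          sample(path_sigs, 1), sample(c("germline", "somatic"), 1)
        )
      }
    }
    if (decoy[i, "clinvar_cnv"]) {
      cv_rows[[length(cv_rows) + 1]] <- add_cv(
        clinvar_sym[i], sample(c("copy number gain", "copy number loss"), 1),
        "Pathogenic", "germline"
      )
    }
    if (decoy[i, "clinvar_conflicting"]) {
      cv_rows[[length(cv_rows) + 1]] <- add_cv(
        clinvar_sym[i], "single nucleotide variant",
        "Conflicting interpretations of pathogenicity", "germline"
      )
    }
  }
  mg_write_tsv(
    dplyr::bind_rows(c(cv_rows, list(tibble::tibble(
      VariationID = character(), Type = character(), GeneSymbol = character(),
      ClinicalSignificance = character(), OriginSimple = character(),
      Assembly = character()
    )))),
    file.path(out_dir, "clinvar.tsv")
  )

  # ---- hgmd.tsv
  hgmd_sym <- sym_for("hgmd")
  hg_rows <- list()
  for (i in seq_len(n)) {
    k <- hgmd_count[i]
    if (k > 0) {
      hg_rows[[length(hg_rows) + 1]] <- tibble::tibble(
        gene = hgmd_sym[i],
        variant_id = sprintf("CM%04d%02d", i, seq_len(k)),
        variant_class = "DM"
      )
    }
    if (decoy[i, "hgmd_dmq"]) {
      hg_rows[[length(hg_rows) + 1]] <- tibble::tibble(
        gene = hgmd_sym[i],
        variant_id = sprintf("CM%04dQ%d", i, seq_len(2)),
        variant_class = "DM?"
      )
    }
  }
  mg_write_tsv(
    dplyr::bind_rows(c(hg_rows, list(tibble::tibble(
      gene = character(), variant_id = character(), variant_class = character()
    )))),
    file.path(out_dir, "hgmd.tsv")
  )

  # ---- PanelApp JSON dumps (three panels per instance)
  pa_sym <- sym_for("panelapp")
  instance_of <- ifelse(
    member[, "panelapp"],
    sample(c("GenomicsEngland", "Australia", "both"), n,
      replace = TRUE, prob = c(0.25, 0.25, 0.5)
    ),
    NA_character_
  )
  panels <- list(
    GenomicsEngland = list(ids = 101:103, dir = "panelapp_ge"),
    Australia = list(ids = 201:203, dir = "panelapp_aus")
  )
  entries <- list(GenomicsEngland = list(), Australia = list())
  add_entry <- function(inst, i, level) {
    pid <- sample(panels[[inst]]$ids, 1)
    entries[[inst]][[length(entries[[inst]]) + 1]] <<- list(
      panel_id = pid, gene = pa_sym[i], level = level
    )
  }
  for (i in seq_len(n)) {
    if (member[i, "panelapp"]) {
      green_level <- sample(3:4, 1)
      if (instance_of[i] %in% c("GenomicsEngland", "both")) {
        add_entry("GenomicsEngland", i, green_level)
      }
      if (instance_of[i] %in% c("Australia", "both")) {
        add_entry("Australia", i, green_level)
      }
    }
    if (decoy[i, "panelapp_amber_red"]) {
      add_entry(sample(names(panels), 1), i, sample(0:2, 1))
    }
  }
  for (inst in names(panels)) {
    pdir <- file.path(out_dir, panels[[inst]]$dir)
    dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
    for (pid in panels[[inst]]$ids) {
      es <- Filter(function(e) e$panel_id == pid, entries[[inst]])
      genes <- lapply(es, function(e) {
        list(entity_name = e$gene, confidence_level = as.character(e$level))
      })
      jsonlite::write_json(
        list(id = pid, name = paste0(inst, " panel ", pid), genes = genes),
        file.path(pdir, sprintf("panel_%d.json", pid)),
        auto_unbox = TRUE, pretty = TRUE
      )
    }
  }

  # ---- gencc.tsv
  gencc_sym <- sym_for("gencc")
  gc_rows <- list()
  for (i in seq_len(n)) {
    if (member[i, "gencc"]) {
      gc_rows[[length(gc_rows) + 1]] <- tibble::tibble(
        gene_symbol = gencc_sym[i], hgnc_id = hgnc_id[i],
        disease = paste("Disease", symbol[i]),
        classification = "Definitive", submitter = "LabA"
      )
    }
    if (decoy[i, "gencc_strong"]) {
      gc_rows[[length(gc_rows) + 1]] <- tibble::tibble(
        gene_symbol = gencc_sym[i], hgnc_id = hgnc_id[i],
        disease = paste("Disease", symbol[i]),
        classification = sample(c("Strong", "Moderate", "Limited"), 1),
        submitter = "LabB"
      )
    }
  }
  mg_write_tsv(
    dplyr::bind_rows(c(gc_rows, list(tibble::tibble(
      gene_symbol = character(), hgnc_id = character(), disease = character(),
      classification = character(), submitter = character()
    )))),
    file.path(out_dir, "gencc.tsv")
  )

  # ---- sysndd.tsv
  sysndd_sym <- sym_for("sysndd")
  sn_rows <- list()
  for (i in seq_len(n)) {
    if (member[i, "sysndd"]) {
      sn_rows[[length(sn_rows) + 1]] <- tibble::tibble(
        symbol = sysndd_sym[i], status = "Definitive",
        disease = paste("NDD phenotype", symbol[i])
      )
    }
    if (decoy[i, "sysndd_limited"]) {
      sn_rows[[length(sn_rows) + 1]] <- tibble::tibble(
        symbol = sysndd_sym[i], status = sample(c("Limited", "Moderate"), 1),
        disease = paste("NDD phenotype", symbol[i])
      )
    }
  }
  mg_write_tsv(
    dplyr::bind_rows(c(sn_rows, list(tibble::tibble(
      symbol = character(), status = character(), disease = character()
    )))),
    file.path(out_dir, "sysndd.tsv")
  )

  gt <- tibble::tibble(
    hgnc_id = hgnc_id,
    symbol = symbol
  )
  for (src in MG_SOURCES) gt[[src]] <- member[, src]
  gt$clinvar_count <- as.integer(clinvar_count)
  gt$hgmd_count <- as.integer(hgmd_count)
  gt$alias_source <- alias_source
  gt$expected_score <- as.integer(rowSums(member))
  gt$expected_inclusion <- gt$expected_score >= 1

  manifest <- list(
    seed = spec$seed,
    n_genes = spec$n_genes,
    membership = if (is.matrix(spec$membership)) "explicit matrix" else as.list(spec$membership),
    clinvar_count_range = spec$clinvar_count_range,
    hgmd_count_range = spec$hgmd_count_range,
    nonmember_count_range = spec$nonmember_count_range,
    decoy_rates = as.list(spec$decoy_rates),
    alias_rate = spec$alias_rate
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  gt
}

#' Paths of a generated universe, in [collect_evidence()] layout
#'
#' @param dir Directory written by [generate_universe()].
#' @return Named list of the seven input paths.
#' @export
universe_paths <- function(dir) {
  list(
    hgnc = file.path(dir, "hgnc.tsv"),
    omim = file.path(dir, "omim.tsv"),
    clinvar = file.path(dir, "clinvar.tsv"),
    hgmd = file.path(dir, "hgmd.tsv"),
    panelapp_ge = file.path(dir, "panelapp_ge"),
    panelapp_aus = file.path(dir, "panelapp_aus"),
    gencc = file.path(dir, "gencc.tsv"),
    sysndd = file.path(dir, "sysndd.tsv")
  )
}

#' Expected panel rows from planted ground truth
#'
#' The oracle: the panel that a correct pipeline must produce from a
#' generated universe — genes with at least one planted membership, scores
#' equal to the number of planted memberships, flags equal to the planted
#' matrix, sorted as [build_panel()] sorts.
#'
#' @param gt Ground-truth tibble from [generate_universe()].
#' @return Tibble with columns `hgnc_id`, `symbol`, `morbidscore` and the
#'   six source flags.
#' @export
expected_panel <- function(gt) {
  rows <- gt[gt$expected_inclusion, c("hgnc_id", "symbol", MG_SOURCES), drop = FALSE]
  rows$morbidscore <- as.integer(gt$expected_score[gt$expected_inclusion])
  rows <- rows[c("hgnc_id", "symbol", "morbidscore", MG_SOURCES)]
  rows[order(rows$symbol, rows$hgnc_id, method = "radix"), , drop = FALSE]
}
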