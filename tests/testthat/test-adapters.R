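# Snapshot parsers and the six inclusion criteria.

omim_assoc <- function(labels, keys = 3L, gene = "AAA") {
  tibble::tibble(
    gene_symbol = gene, mim_number = 100001L,
    phenotype_label = labels,
    mapping_key = as.integer(rep_len(keys, length(labels)))
  )
}

test_that("OMIM phenotype cells parse into per-entry associations", {
  dir <- withr::local_tempdir()
  f <- write_lines_tsv(file.path(dir, "omim.tsv"), c(
    "Gene Symbols\tMIM Number\tPhenotypes",
    "AAA\t100001\tHoloprosencephaly 5, 609637 (3)",
    "BBB\t100002\t",
    "CCC\t100003\tDisease one, 611111 (3); {Asthma, susceptibility to}, 600807 (2)"
  ))
  a <- parse_omim(f)
  expect_equal(nrow(a), 3) # 1 + 0 + 2 entries
  expect_equal(a$phenotype_label[1], "Holoprosencephaly 5")
  expect_equal(a$mapping_key[1], 3L)
  expect_false("BBB" %in% a$gene_symbol)
  expect_equal(sum(a$gene_symbol == "CCC"), 2)
  expect_equal(a$phenotype_label[a$gene_symbol == "CCC"][2], "{Asthma, susceptibility to}")

  # malformed mapping-key tail: association kept, key NA, warning logged
  g <- write_lines_tsv(file.path(dir, "omim2.tsv"), c(
    "Gene Symbols\tMIM Number\tPhenotypes",
    "AAA\t100001\tSome disease without key"
  ))
  expect_warning(b <- parse_omim(g), "malformed mapping key")
  expect_equal(nrow(b), 1)
  expect_true(is.na(b$mapping_key))
})

test_that("OMIM criterion excludes provisional, susceptibility, nondisease and non-3/4 keys", {
  cases <- list(
    list(assoc = omim_assoc("Holoprosencephaly 5"), met = TRUE, count = 1L),
    list(assoc = omim_assoc("{Asthma, susceptibility to}"), met = FALSE, count = 0L),
    list(assoc = omim_assoc("?Neurodevelopmental disorder"), met = FALSE, count = 0L),
    list(assoc = omim_assoc("[Blood group, Junior system]"), met = FALSE, count = 0L),
    list(assoc = omim_assoc("Linkage-only disease", keys = 2L), met = FALSE, count = 0L),
    list(assoc = omim_assoc("Chromosomal syndrome", keys = 4L), met = TRUE, count = 1L),
    list(
      assoc = omim_assoc(c("?Provisional", "Real disease", "{Risk}")),
      met = TRUE, count = 1L
    ),
    list(assoc = omim_assoc(character(0)), met = FALSE, count = 0L)
  )
  for (cs in cases) {
    ev <- omim_criterion(cs$assoc)
    expect_equal(ev$met, cs$met)
    expect_equal(ev$count, cs$count)
    expect_equal(ev$source, "omim")
  }
  # mapping keys are configurable
  ev <- omim_criterion(omim_assoc("Linkage-only disease", keys = 2L),
    mapping_keys = 1:4
  )
  expect_true(ev$met)
})

test_that("ClinVar parser deduplicates per-assembly rows and expands multi-gene cells", {
  dir <- withr::local_tempdir()
  f <- write_lines_tsv(file.path(dir, "cv.tsv"), c(
    paste("VariationID", "Type", "GeneSymbol", "ClinicalSignificance",
      "OriginSimple", "Assembly",
      sep = "\t"
    ),
    "1\tsingle nucleotide variant\tAAA\tPathogenic\tgermline\tGRCh37",
    "1\tsingle nucleotide variant\tAAA\tPathogenic\tgermline\tGRCh38",
    "2\tsingle nucleotide variant\tAAA;BBB\tLikely pathogenic\tgermline\tGRCh38",
    "abc\tsingle nucleotide variant\tAAA\tPathogenic\tgermline\tGRCh38"
  ))
  expect_warning(recs <- parse_clinvar(f), "non-integer VariationID")
  expect_equal(nrow(recs), 3) # dedup of vid 1 + expansion of vid 2; bad row skipped
  expect_equal(sort(recs$gene_symbol), c("AAA", "AAA", "BBB"))
  expect_equal(sum(recs$variation_id == 1), 1)

  empty <- write_lines_tsv(file.path(dir, "cv0.tsv"), paste(
    "VariationID", "Type", "GeneSymbol", "ClinicalSignificance",
    "OriginSimple", "Assembly",
    sep = "\t"
  ))
  expect_equal(nrow(parse_clinvar(empty)), 0)
})

test_that("ClinVar criterion counts (likely) pathogenic non-CNV variants, threshold 4", {
  cases <- list(
    list(rec = cv_rec(4, "Pathogenic"), met = TRUE, count = 4L),
    list(rec = cv_rec(3, "Pathogenic"), met = FALSE, count = 3L), # sharp at 4
    list(
      rec = dplyr::bind_rows(
        cv_rec(3, "Pathogenic"),
        cv_rec(1, "Pathogenic", type = "copy number loss", start_id = 10L)
      ),
      met = FALSE, count = 3L
    ),
    list(rec = cv_rec(4, "Likely pathogenic", origin = "somatic"), met = TRUE, count = 4L),
    list(rec = cv_rec(4, "Pathogenic/Likely pathogenic"), met = TRUE, count = 4L),
    list(rec = cv_rec(4, "Conflicting interpretations of pathogenicity"), met = FALSE, count = 0L),
    list(rec = cv_rec(4, "Benign"), met = FALSE, count = 0L),
    list(rec = cv_rec(4, "Pathogenic", type = "copy number gain"), met = FALSE, count = 0L),
    list(rec = cv_rec(4, "Pathogenic", type = "Deletion"), met = TRUE, count = 4L)
  )
  for (cs in cases) {
    ev <- clinvar_criterion(cs$rec)
    expect_equal(ev$met, cs$met)
    expect_equal(ev$count, cs$count)
  }
  expect_false(clinvar_criterion(NULL)$met)
})

test_that("HGMD parser keeps known classes; criterion defaults to DM with threshold 4", {
  dir <- withr::local_tempdir()
  f <- write_lines_tsv(file.path(dir, "hgmd.tsv"), c(
    "gene\tvariant_id\tvariant_class",
    paste0("AAA\tCM00", 1:5, "\tDM"),
    "AAA\tCM006\tXX"
  ))
  expect_warning(recs <- parse_hgmd(f), "unknown variant class")
  expect_equal(nrow(recs), 5)

  expect_true(hgmd_criterion(hg_rec(4))$met)
  expect_false(hgmd_criterion(hg_rec(3))$met) # sharp at 4
  mixed <- dplyr::bind_rows(hg_rec(3), hg_rec(2, class = "DM?"))
  ev <- hgmd_criterion(mixed)
  expect_false(ev$met)
  expect_equal(ev$count, 3L)
  # DM? admissible via config
  ev2 <- hgmd_criterion(mixed, classes = c("DM", "DM?"))
  expect_true(ev2$met)
  expect_equal(ev2$count, 5L)
  expect_equal(hgmd_criterion(NULL)$count, 0L)
})

test_that("PanelApp JSON dumps parse to per-(panel, gene) entries", {
  dir <- withr::local_tempdir()
  pdir <- file.path(dir, "panels")
  dir.create(pdir)
  jsonlite::write_json(
    list(id = 7, name = "Test panel", genes = list(
      list(entity_name = "AAA", confidence_level = "3"),
      list(entity_name = "BBB", confidence_level = "1")
    )),
    file.path(pdir, "p7.json"),
    auto_unbox = TRUE
  )
  e <- parse_panelapp(pdir, "GenomicsEngland")
  expect_equal(nrow(e), 2)
  expect_identical(e$confidence_level, c(3L, 1L)) # numeric string coerced
  expect_equal(e$panel_id, c(7L, 7L))

  empty <- file.path(dir, "empty")
  dir.create(empty)
  expect_equal(nrow(parse_panelapp(empty, "Australia")), 0)

  writeLines("{not json", file.path(pdir, "bad.json"))
  expect_error(parse_panelapp(pdir, "GenomicsEngland"), "bad\\.json",
    class = "mg_format_error"
  )
})

test_that("PanelApp criterion: green (level >= 3) in either instance qualifies", {
  expect_true(panelapp_criterion(pa_entry(3))$met)
  expect_false(panelapp_criterion(pa_entry(2))$met) # sharp at 3
  expect_false(panelapp_criterion(dplyr::bind_rows(pa_entry(1), pa_entry(2)))$met)
  aus <- panelapp_criterion(pa_entry(3, instance = "Australia", panel = "Mendeliome"))
  expect_true(aus$met)
  expect_match(aus$detail, "AUS:Mendeliome")
  both <- panelapp_criterion(dplyr::bind_rows(
    pa_entry(4, panel = "Panel GE"), pa_entry(3, instance = "Australia", panel = "Panel AUS")
  ))
  expect_equal(both$count, 2L)
  expect_match(both$detail, "GE:Panel GE")
})

test_that("GenCC criterion accepts only Definitive; SysNDD Definitive/Definite", {
  gc <- function(cls) {
    tibble::tibble(
      gene_symbol = "AAA", hgnc_id = "HGNC:1",
      disease_label = "D", classification = cls, submitter = "Lab"
    )
  }
  expect_true(gencc_criterion(gc("Definitive"))$met)
  expect_true(gencc_criterion(gc("DEFINITIVE"))$met) # case-insensitive
  expect_false(gencc_criterion(gc(c("Strong", "Moderate")))$met)
  expect_false(gencc_criterion(NULL)$met)

  sn <- function(status) {
    tibble::tibble(gene_symbol = "AAA", status = status, disease_label = "D")
  }
  expect_true(sysndd_criterion(sn("Definitive"))$met)
  expect_true(sysndd_criterion(sn("definite"))$met)
  expect_false(sysndd_criterion(sn("Limited"))$met)
  expect_false(sysndd_criterion(NULL)$met)
})

test_that("criteria are order-invariant in (met, count)", {
  set.seed(11)
  recs <- dplyr::bind_rows(
    cv_rec(5, "Pathogenic"),
    cv_rec(2, "Benign", start_id = 20L),
    cv_rec(1, "Pathogenic", type = "copy number gain", start_id = 30L)
  )
  base <- clinvar_criterion(recs)
  for (i in 1:5) {
    perm <- recs[sample(nrow(recs)), ]
    ev <- clinvar_criterion(perm)
    expect_equal(ev$met, base$met)
    expect_equal(ev$count, base$count)
  }
  hrecs <- dplyr::bind_rows(hg_rec(4), hg_rec(3, class = "DP"))
  hbase <- hgmd_criterion(hrecs)
  for (i in 1:5) {
    ev <- hgmd_criterion(hrecs[sample(nrow(hrecs)), ])
    expect_equal(ev[c("met", "count")], hbase[c("met", "count")])
  }
})
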