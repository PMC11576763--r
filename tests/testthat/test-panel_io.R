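# Panel assembly, serialization round-trip, byte determinism, diffing.

test_that("build_panel keeps score >= 1, sorts by symbol, validates labels", {
  ev <- dplyr::bind_rows(
    evidence_row(rep(FALSE, 6), id = "HGNC:3", symbol = "ZZZ"),
    evidence_row(rep(TRUE, 6), id = "HGNC:2", symbol = "BBB"),
    evidence_row(c(TRUE, rep(FALSE, 5)), id = "HGNC:1", symbol = "CCC")
  )
  p <- build_panel(ev, "v2024_01")
  expect_equal(nrow(p$rows), 2) # score-0 gene omitted
  expect_equal(p$rows$symbol, c("BBB", "CCC")) # sorted
  expect_equal(p$rows$morbidscore, c(6L, 1L))

  expect_error(build_panel(ev, "2024-01"), class = "mg_argument_error")
  expect_error(
    build_panel(dplyr::bind_rows(ev[2, ], ev[2, ]), "v2024_01"),
    class = "mg_integrity_error"
  )
  empty <- build_panel(ev[0, ], "v2024_01")
  expect_equal(nrow(empty$rows), 0) # empty panel is valid
})

test_that("write/read round-trips a panel on all fields", {
  u <- build_universe(fixture_spec(n_genes = 40, seed = 77))
  dir <- withr::local_tempdir()
  tsv <- write_panel(u$panel, dir)
  expect_true(file.exists(file.path(dir, "v2024_01.meta.json")))
  back <- read_panel(tsv)
  expect_equal(back$label, u$panel$label)
  expect_equal(back$build_date, u$panel$build_date)
  expect_equal(back$rows, u$panel$rows)
  expect_equal(back$source_meta, u$panel$source_meta)
})

test_that("panel TSV output is byte-identical across repeated builds", {
  spec <- fixture_spec(n_genes = 60, seed = 88)
  dirs <- replicate(2, withr::local_tempdir())
  bytes <- lapply(dirs, function(d) {
    generate_universe(spec, file.path(d, "u"))
    built <- build_panel_from_dir(file.path(d, "u"), "v2024_02",
      build_date = as.Date("2024-02-01")
    )
    write_panel(built$panel, file.path(d, "out"))
    readBin(file.path(d, "out", "v2024_02.tsv"), "raw", n = 1e6)
  })
  expect_identical(bytes[[1]], bytes[[2]])
})

test_that("reading a corrupted panel raises integrity errors", {
  u <- build_universe(fixture_spec(n_genes = 20, seed = 5))
  dir <- withr::local_tempdir()
  tsv <- write_panel(u$panel, dir)
  lines <- readLines(tsv)

  dup <- c(lines, lines[2]) # duplicate hgnc_id (and broken sort)
  bad1 <- file.path(dir, "bad1.tsv")
  writeLines(dup, bad1)
  file.copy(sub("\\.tsv$", ".meta.json", tsv), file.path(dir, "bad1.meta.json"))
  expect_error(read_panel(bad1), class = "mg_integrity_error")

  # score inconsistent with flags
  row2 <- strsplit(lines[2], "\t")[[1]]
  row2 <- c(row2, rep("", 15 - length(row2))) # keep trailing empty details
  row2[3] <- "6"
  flags <- row2[4:9] == "TRUE"
  if (sum(flags) == 6) row2[3] <- "1"
  bad2 <- file.path(dir, "bad2.tsv")
  writeLines(c(lines[1], paste(row2, collapse = "\t")), bad2)
  file.copy(sub("\\.tsv$", ".meta.json", tsv), file.path(dir, "bad2.meta.json"))
  expect_error(read_panel(bad2), "morbidscore", class = "mg_integrity_error")
})

test_that("diff identifies additions, removals and score changes; algebra holds", {
  u <- build_universe(fixture_spec(n_genes = 50, seed = 9), label = "v2024_01")
  p1 <- u$panel

  # planted edits: drop 2 genes, change 3 scores, add 1 gene
  rows <- p1$rows
  removed_ids <- rows$hgnc_id[c(1, 5)]
  rows2 <- rows[-c(1, 5), ]
  changed_ids <- character(0)
  for (i in head(which(rows2$morbidscore < 6), 3)) {
    src <- panel_sources()[!unlist(rows2[i, panel_sources()])][1]
    rows2[i, src] <- TRUE
    rows2$morbidscore[i] <- rows2$morbidscore[i] + 1L
    changed_ids <- c(changed_ids, rows2$hgnc_id[i])
  }
  new_row <- rows[1, ]
  new_row$hgnc_id <- "HGNC:99999"
  new_row$symbol <- "ZZZNEW"
  rows2 <- dplyr::bind_rows(rows2, new_row)
  rows2 <- rows2[order(rows2$symbol, rows2$hgnc_id, method = "radix"), ]
  p2 <- build_panel(
    {
      ev <- tibble::tibble(hgnc_id = rows2$hgnc_id, symbol = rows2$symbol)
      for (src in panel_sources()) {
        ev[[paste0(src, "_met")]] <- rows2[[src]]
        ev[[paste0(src, "_count")]] <- as.integer(rows2[[src]])
        ev[[paste0(src, "_detail")]] <- ""
      }
      ev
    },
    "v2024_02"
  )

  d <- diff_panels(p1, p2)
  expect_equal(d$added, "HGNC:99999")
  expect_equal(d$removed, sort(removed_ids))
  expect_equal(sort(d$score_changed$hgnc_id), sort(changed_ids))
  expect_true(all(d$score_changed$new_score == d$score_changed$old_score + 1))

  # |b| = |a| - |removed| + |added|; diff symmetry; self-diff empty
  expect_equal(nrow(p2$rows), nrow(p1$rows) - length(d$removed) + length(d$added))
  rev <- diff_panels(p2, p1)
  expect_equal(rev$removed, d$added)
  expect_equal(rev$added, d$removed)
  self <- diff_panels(p1, p1)
  expect_equal(length(self$added) + length(self$removed) + nrow(self$score_changed), 0)
})
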