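# morbidpanel

Diagnostic labs overlaying virtual gene panels on exome data face a
trade-off: narrow phenotype-specific panels miss relevant genes, while
maintaining one broad panel of every gene with minimally sufficient
evidence of disease causality is a curation burden that only large
consortia can shoulder. `morbidpanel` automates that broad panel: it
aggregates gene-level evidence from local snapshots of six databases —
OMIM, ClinVar, HGMD, PanelApp (Genomics England and Australia instances),
SysNDD and GenCC — and emits a versioned, diffable, filterable gene panel
for use as a first-in-line in silico panel in routine diagnostics.

## The Morbidscore

Each source awards at most **one point** to a gene's Morbidscore
*S* ∈ {0, …, 6}, via a source-specific inclusion criterion:

| Source   | Criterion (one point if…) |
|----------|---------------------------|
| OMIM     | ≥ 1 phenotype association that is not provisional (`?`), not a susceptibility (`{…}`) or nondisease (`[…]`) entry, with mapping key 3 or 4 |
| ClinVar  | ≥ 4 deduplicated (likely) pathogenic variants, somatic included, copy-number variants excluded |
| HGMD     | ≥ 4 pathogenic (DM) variants |
| PanelApp | green status (confidence level ≥ 3) in ≥ 1 panel of either instance |
| SysNDD   | ≥ 1 entity with status Definitive |
| GenCC    | ≥ 1 submission classified Definitive |

A gene enters the panel iff *S* ≥ 1; users filter more stringently
downstream with a minimum-score threshold. Symbols from all sources are
first harmonized against an HGNC-style table (tier precedence
approved > previous > alias; ambiguous matches are dropped and logged)
so evidence lands on stable accessions.

Because the real databases are licensed and point-in-time, the package
ships a synthetic snapshot generator that emulates all seven input
dialects around a planted gene×source ground-truth matrix — including
decoy records for every exclusion rule — so the entire pipeline is
validated end-to-end against a known expected panel.

## Worked example

```r
library(morbidpanel)

dir <- file.path(tempdir(), "universe")
gt <- generate_universe(fixture_spec(n_genes = 100, seed = 42), dir)
built <- build_panel_from_dir(dir, "v2024_10", build_date = as.Date("2024-10-01"))
panel <- built$panel
panel
#> <panel_version> v2024_10 (2024-10-01): 99 genes

head(panel$rows[c("hgnc_id", "symbol", "morbidscore", panel_sources())], 4)
#> # A tibble: 4 × 9
#>   hgnc_id    symbol   morbidscore omim  clinvar hgmd  panelapp sysndd gencc
#>   <chr>      <chr>          <int> <lgl> <lgl>   <lgl> <lgl>    <lgl>  <lgl>
#> 1 HGNC:10001 GENE0001           3 FALSE FALSE   FALSE TRUE     TRUE   TRUE
#> 2 HGNC:10002 GENE0002           4 FALSE TRUE    TRUE  TRUE     FALSE  TRUE
#> 3 HGNC:10003 GENE0003           3 TRUE  TRUE    FALSE TRUE     FALSE  FALSE
#> 4 HGNC:10004 GENE0004           3 FALSE TRUE    TRUE  TRUE     FALSE  FALSE

score_distribution(panel)$counts
#>  1  2  3  4  5  6
#>  6 20 46 18  9  0

head(exclusive_intersections(panel)$rows, 3)
#> # A tibble: 3 × 2
#>   combination              count
#>   <chr>                    <int>
#> 1 omim+hgmd+panelapp           9
#> 2 hgmd+panelapp+gencc          8
#> 3 omim+hgmd+panelapp+gencc     6

nrow(filter_by_min_score(panel$rows, 4))
#> [1] 27
```

Of the 100 planted genes, 99 satisfied at least one criterion and entered
the panel (one gene drew no source membership). Each row shows which of
the six sources support the gene; the score distribution and the
exclusive (UpSet-style) intersections summarize how evidence overlaps
across sources, and `filter_by_min_score` keeps the 27 genes supported by
at least four databases. `write_panel()` serializes the panel as a TSV
plus JSON metadata sidecar with byte-identical output for identical
inputs; `diff_panels()` tracks genes added, removed and rescored between
monthly versions.

A command-line front end with subcommands `build`, `diff`, `stats`,
`filter` and `simulate` is installed at `inst/cli/morbidpanel.R`
(`system.file("cli", "morbidpanel.R", package = "morbidpanel")`).

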