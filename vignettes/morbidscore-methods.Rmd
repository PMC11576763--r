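---
title: "Evidence aggregation and the Morbidscore: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidence aggregation and the Morbidscore: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`morbidpanel` implements a deliberately simple evidence-aggregation
model for building a broad diagnostic gene panel. For each gene $g$ and
each of six source databases $s$, a binary verdict $m_{g,s}$ records
whether the source's inclusion criterion is met. The Morbidscore is the
plain sum

$$ S_g = \sum_{s} m_{g,s} \in \{0, \dots, 6\}, $$

and a gene is included in the panel iff $S_g \ge 1$. Two modelling
assumptions are built in:

* **One point per source.** A source contributes at most one point no
  matter how many qualifying records it holds (a gene green in ten
  PanelApp panels scores the same panelapp point as a gene green in
  one). This makes the score an interpretable count of independent-ish
  evidence streams rather than a record tally dominated by the largest
  database.
* **Inclusion at a single point.** Genes supported by only one source
  are kept — deliberately so: such a gene may still carry the exact
  reported variant seen in a patient, and excluding it risks false
  negatives. The cost is that limited-evidence genes ("genes of
  uncertain significance") enter the panel; the Morbidscore itself is
  the user's stringency dial (`filter_by_min_score()`).

Scores are always recomputed from the six flags at build time and a
panel file whose stored score disagrees with its flags is rejected on
read, which removes a whole class of consistency bugs.

## The six criteria and their parameters

| Parameter | Default | Meaning |
|---|---|---|
| `omim_mapping_keys` | 3, 4 | OMIM mapping keys that qualify (3 = molecular basis known, 4 = chromosomal). Keys 1–2 are linkage/phenotype-only evidence that is not diagnostically attributable to the gene, so they are excluded by default. |
| `clinvar_min` | 4 | Minimum deduplicated (likely) pathogenic ClinVar variants. |
| `hgmd_min` | 4 | Minimum qualifying HGMD variants. |
| `hgmd_classes` | `DM` | HGMD classes counted as pathogenic. `DM?` is explicitly *questioned* pathogenicity and excluded by default, but admissible via configuration. |
| `panelapp_min_level` | 3 | Confidence level at which a PanelApp entry counts as green. Level 3 is the lowest green tier in both instances. |

Unit-less conventions that are fixed rather than parameters:

* **OMIM exclusions.** Phenotype labels prefixed `?` (provisional) or
  wrapped in `{…}` (susceptibility) are excluded; so are `[…]`
  (nondisease) labels, which mark traits like blood groups that are not
  diseases at all. A malformed mapping-key parenthetical keeps the
  association with a null key (which can never qualify) and logs a
  warning, rather than silently dropping the row.
* **ClinVar significance.** The predicate is a case-insensitive
  substring test: contains "pathogenic" and not "conflicting". This
  captures the compound strings ("Pathogenic/Likely pathogenic")
  without enumerating them, while "Conflicting interpretations of
  pathogenicity" — which contains "pathogenic" as a substring — never
  counts. Variant origin is ignored (somatic counts); copy-number
  gains/losses are excluded; review status (star rating) plays no role.
* **ClinVar deduplication.** variant_summary-style tables list each
  variant once per assembly; counting raw rows would double-count, so
  records are deduplicated by (VariationID, gene) before counting.
  Multi-gene cells expand to one record per gene first, so a variant can
  legitimately count once for each gene it overlaps.
* **GenCC "Definitive".** GenCC's controlled vocabulary has no
  "definite" class; the closest term is "Definitive", matched exactly
  after case folding. "Strong" does not qualify — admitting it would
  change the criterion from "settled" to "probably settled", and the
  conservative reading keeps the six criteria parallel (each demands the
  source's own top tier or a hard count). SysNDD accepts both
  "Definitive" and "Definite", which both occur in exports.

## Symbol harmonization

The six sources emit gene symbols of varying vintage. Every symbol is
resolved against an HGNC-style table with tier precedence
**approved > previous > alias**, case-sensitively after whitespace
trimming (HGNC symbols are case-significant). A symbol matching the
previous/alias symbols of two or more genes at its best tier is
*unmapped with an ambiguity flag* rather than attributed arbitrarily:
silently crediting evidence to the wrong gene is worse than dropping a
record, and the per-source unmapped tallies in the build log surface
every drop. Records that fail resolution are excluded from scoring.
This tiered resolver is this package's own design; aggregating by raw
symbol string across sources is not reproducible as symbols drift.

## The synthetic universe generator

Real snapshots of the six databases are licensed and point-in-time, so
the test bed is a generator (`generate_universe()`) that emits all seven
input dialects around a planted gene×source membership matrix and
returns the matrix as ground truth. It is constructive in both
directions:

* a gene planted as a member of a source receives records that satisfy
  that source's criterion (e.g. 4–8 pathogenic SNVs, each emitted on
  both assemblies so deduplication is always exercised);
* a non-member receives only sub-threshold records (0–3 qualifying
  variants) and *decoys* — one class per exclusion rule: provisional,
  susceptibility and nondisease OMIM lines, CNV and
  conflicting-significance ClinVar lines, `DM?` HGMD lines, amber/red
  PanelApp entries, Strong GenCC lines, Limited SysNDD lines. The
  exclusions are the substance of the criteria, so every negative path
  has coverage.

A fraction of genes (`alias_rate`, default 0.1 in the validation
suites) is emitted under an alias symbol in one randomly chosen source,
exercising harmonization end-to-end. The default membership
probabilities (omim .60, clinvar .55, hgmd .55, panelapp .60, sysndd
.15, gencc .40) were chosen once to mirror the qualitative structure of
real panels — four broad sources dominating, a phenotype-specific
database (SysNDD) much smaller — and are not tuned further.

**What passing tests show and do not show.** Exact agreement between
built panels and the planted oracle demonstrates that parsing,
harmonization, criteria, scoring, serialization and statistics are
mutually consistent and correct *for the documented dialects*. It does
not demonstrate robustness to the full messiness of real exports
(unusual phenotype punctuation, symbol collisions beyond planted
aliases, encoding issues), nor does it reproduce the marginal
distributions of the real databases — absolute gene counts from real
snapshots are out of scope by construction.

## Numerical and formatting choices

* **Determinism.** Panel TSVs are written with a fixed column order,
  LF line endings, no quoting, and fields validated tab-free; rows are
  sorted by symbol with hgnc_id as tiebreak using C-locale (radix)
  ordering, so identical inputs give byte-identical files on any
  machine. The generator is fully seeded; the same seed yields
  byte-identical snapshot files.
* **Degenerate inputs.** Empty evidence builds a valid empty panel;
  empty snapshot files parse to empty record sets; a criterion applied
  to zero records returns met = FALSE, count = 0. The minimum-score
  filter accepts k = 0 (identity) through k = 7 (one above the maximum,
  so "empty panel" is expressible).
* **Exclusive intersections.** The UpSet-style table assigns each gene
  to exactly the combination equal to its set of supporting sources, so
  intersection counts sum to the panel size and per-source marginals
  are recoverable; rows sort by count descending with lexicographic
  tie-break on the combination label.

## Validation problem sizes

The oracle-equivalence suite runs 20 randomly parameterized universes
of 50–500 genes with all decoy classes active and 10% alias emission;
the remaining suites use universes of 20–200 genes. The acceptance
script builds a 500-gene reference universe. These sizes give every
combinatorial path (all 64 source combinations, all nine decoy classes)
many chances to occur while a full test run stays in the minutes range.

## Known limitations

* Gene-level only: no variant-level output, inheritance modes, or
  phenotype annotations — by design, resolution is traded for breadth
  and automation.
* The criteria treat sources as independent, which they are not (GenCC
  aggregates several of the others); the score is a count of supporting
  databases, not a calibrated probability of disease association.
* Snapshot dialects are fixed; live APIs, licensing-restricted content
  handling and website hosting are out of scope.
* OMIM multi-symbol cells contribute evidence only via their first
  (canonical) symbol; the remainder are aliases of the same gene and
  would double-count.
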