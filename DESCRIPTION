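Package: morbidpanel
Title: Evidence-Aggregated Gene Panel Curation with the Morbidscore
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a broad diagnostic gene panel by aggregating gene-level
    evidence from local snapshots of six clinical genomics databases (OMIM,
    ClinVar, HGMD, PanelApp, SysNDD, GenCC). Each source contributes at most
    one point to a per-gene Morbidscore (0-6) via a source-specific inclusion
    criterion; genes scoring at least one point enter a versioned, diffable
    panel. Includes HGNC-based symbol harmonization, panel serialization with
    reproducible byte-identical output, version diffing, summary statistics
    (score distribution, exclusive UpSet-style source intersections, version
    trend), a synthetic snapshot generator with planted ground truth for
    end-to-end validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
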