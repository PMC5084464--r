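Package: annochron
Title: Longitudinal Analysis of Transcript Biotype Annotations Across
    GENCODE Releases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to track how transcript annotations evolve across a
    chronological series of GENCODE GTF releases. Harmonizes transcript
    identifiers across releases (pseudo-autosomal duplicate collapse and
    Havana/Ensembl OTTHUMT-to-ENST reconciliation), builds a transcript by
    release biotype-code matrix, and derives longitudinal statistics:
    per-release additions and deletions, biotype transitions, annotation
    consistency, moonlighting protein-coding/lncRNA identities,
    biotype-set stability, exon-union genome coverage, and overlap of
    deleted genes with an HGNC symbol set. Includes Sankey-flow and
    growth-table exports and a synthetic multi-release corpus generator
    with a ground-truth ledger so the whole pipeline is testable without
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
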