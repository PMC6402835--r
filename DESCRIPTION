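Package: phylogrn
Title: Evolutionary Age-Aware Analysis of Somatic Mutations in Gene
    Regulatory Networks
Version: 0.99.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Relates the evolutionary ages of human genes (phylostrata) to
    recurrent somatic alterations across tumor cohorts. Implements recurrence
    calling for point mutations and copy-number aberrations, per-phylostratum
    enrichment fractions with Jonckheere-Terpstra ordered trend tests,
    classification of gene-regulatory-network regulators by the age composition
    of their targets, mutation-to-expression impact scoring, regulator/target
    copy-number mutual-exclusivity analysis, and cell-line dependency and drug
    sensitivity association screens. Ships a fully seeded synthetic-data
    generator emulating the statistical structure of the tumor-cohort inputs so
    the whole pipeline runs and tests without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    GenomicRanges,
    igraph,
    IRanges,
    jsonlite,
    methods,
    S4Vectors,
    stats,
    SummarizedExperiment,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
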