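Package: radmod
Title: Analysis of Pooled CRISPRi Radiation Modifier Screens
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for analysing pooled CRISPR interference (CRISPRi)
    radiation modifier screens in cancer cells, from raw sgRNA count
    tables to per-gene screen scores and radiation-sensitizer calls.
    Implements control-centered log2 enrichment phenotypes, Mann-Whitney
    gene scoring against non-targeting controls, empirical false
    discovery rate calibration with negative-control pseudogenes,
    filtering of hits whose TSS lies near an expressed protein-coding
    gene, sensitizer scoring across paired (+/- radiation) screens,
    doubling-time estimation, and a Bliss-independence synergy test for
    validation growth assays. A negative-binomial screen simulator with
    known ground truth supports end-to-end testing and calibration.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    withr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
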