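Package: captureBias
Title: Audit of Exome Capture Kit Coverage Bias in Cancer Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects genes whose absence of somatic mutation calls in a
    tumor cohort is explained by insufficient sequencing coverage rather
    than biology, attributes the insufficiency to the whole-exome capture
    kit used for each sample, and quantifies capture-design shortfall
    against canonical exon and CDS annotations. Provides MAF cohort
    screening for suspicious mutational absence, read-filtered per-base
    depth audits with configurable sufficiency thresholds, capture-BED
    versus gene-model overlap audits, kit-stratified insufficiency
    summaries, and a fully deterministic synthetic-data generator that
    plants coverage-censored mutations so every pipeline stage can be
    validated end to end without access to controlled tumor data.
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
    GenomicAlignments,
    Rsamtools,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
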