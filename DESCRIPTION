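Package: crossmeth
Title: PCA-Guided Differential DNA Methylation Analysis for Crossover
    Exposure Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for genome-scale DNA methylation array data
    from two-arm crossover exposure studies with repeated measures.
    Implements probe-level quality filtering, quantile normalization,
    colour-channel and probe-type (peak-based) correction, principal
    component decomposition with a covariate association screen,
    loading-based feature selection, blood cell-composition confound
    filtering, per-probe linear mixed-effects modelling with arm-specific
    pre/post contrasts, Storey q-value false discovery control, effect
    summaries on the beta scale, carryover and genotype-stratified tests,
    and repeat-element (Alu/LINE1) and microRNA locus overlap analyses.
    Includes a synthetic-data generator that emulates the crossover design
    with planted exposure effects, cell-mixture and demographic covariate
    signals, probe-type dichotomy and detection failures, so the whole
    pipeline is testable without access to raw array data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    nlme,
    limma,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
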