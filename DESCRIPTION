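Package: melacross
Title: Cross-Species Expression Concordance for Pigment-Cell Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for comparing fish pigment-cell-tumor
    RNA-seq transcriptomes with human melanoma microarray data. Implements
    RPKM quantification with expression gating, median-of-ratios size factors,
    a no-replicate conditional negative-binomial differential-expression test
    with a pooled ("blind") variance model, quantile normalization and an
    empirical-Bayes moderated t-test for two-group microarray designs, a
    within-gene correlation-range statistic (RC_gene) for isoform-switch
    detection, symbol-based ortholog joining with conserved-signature
    extraction and motif-overlap counting, hypergeometric over-representation,
    and a seeded synthetic-data generator with planted truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    limma,
    DESeq2,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
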