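Package: methylaging
Title: Epigenetic Clocks, PRC2 Methylation Scores and Mutation-Stratified
    Aging Analysis for Methylation Array Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing DNA methylation aging signals in leukemia-style
    cohorts profiled on Illumina 450K-type arrays. Applies linear epigenetic
    clocks (pan-tissue style with log-linear adult calibration, and
    causality-enriched identity-calibration clocks) and computes epigenetic age
    acceleration as the difference from chronological age; performs iterative
    PCA-based cohort outlier filtering, BMIQ-style beta-mixture quantile
    normalization and M-value transformation; scores mean methylation over
    Polycomb repressive complex 2 (PRC2) binding regions and stratifies
    PRC2-bound low-methylated regions across age groups; calls differentially
    methylated CpGs between mutation-defined groups with empirical-Bayes
    variance moderation; tests transcription-factor binding-region enrichment
    among differential CpGs by hypergeometric tests with FDR control; and
    provides the cohort-level inferential toolbox (Mann-Whitney comparisons,
    partial correlations controlling age, Kaplan-Meier and log-rank survival
    stratification). A seeded synthetic-cohort generator emulates the
    statistical structure every stage assumes, for testing and power studies.
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
    GenomicRanges,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    limma,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
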