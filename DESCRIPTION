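Package: vaxsig
Title: Multi-Tissue Transcriptomic and Serum-Protein Signatures of
    Vaccine-Induced Inflammation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A reproducible pipeline for discovering blood-measurable
    biomarkers of vaccine reactogenicity from multi-tissue expression
    profiling.  Implements microarray-style preprocessing (normexp
    background correction, quantile normalization), per-gene linear
    models with a dual-control interaction contrast and empirical-Bayes
    moderated t-statistics, rank-based CERNO gene-set enrichment with
    rank-sum AUC effect sizes, signed weighted co-expression modules
    with eigengenes and module-trait correlations, cross-tissue
    concordance (disco) scoring and top-gene biomarker selection, and
    serum-analyte statistics (fold change versus saline, two-way ANOVA
    with Dunnett comparisons, time-course AUC, transcript-protein
    correlation).  Ships a synthetic-study generator with known ground
    truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    mvtnorm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    limma,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
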