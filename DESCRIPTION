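Package: regulatlas
Title: Multi-Tissue Gene Regulation Atlas Construction and Trait Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building a multi-tissue atlas of gene regulatory
    variation in structured plant populations and linking it to complex
    traits. Implements tissue-specificity scoring from pooled-sample
    t-statistics, mixed-linear-model association scans with a genomic
    kinship random effect (EMMAX-style and exact modes), stepwise
    conditional analysis, effective-marker-number significance thresholds,
    REML variance components with arbitrary relationship matrices,
    transcriptome variance partitioning via an omics relationship matrix,
    mixed-model transcriptome-wide association, LD-based eQTL clustering,
    distance colocalization with published trait QTL, and summary-based
    Mendelian randomization with the HEIDI heterogeneity test. A synthetic
    data module generates LD-blocked genotypes with population structure,
    multi-tissue expression with planted cis/trans regulatory effects and
    latent factors, and traits with recorded ground truth, so the whole
    pipeline is testable end to end without external downloads.
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
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
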