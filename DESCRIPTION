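Package: popmeth
Title: Population Epigenomics: Differential Methylation, QTL Mapping, and
    Causal Mediation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative population-epigenomics toolkit for two-cohort
    studies of DNA methylation, genotype, and gene expression. Implements
    differential methylation between ancestry groups with empirical-Bayes
    variance moderation, cis/trans meQTL and eQTL/eQTM mapping with
    dual-test significance and permutation-derived FDR thresholds, stepwise
    conditional fine-mapping, population-genetic summaries (derived-allele
    frequencies, Hudson FST, the ExpDiff genetic-contribution ratio),
    Bayesian model selection for population-specific genetic effects,
    LD-aware frequency-matched resampling enrichment against GWAS catalogs,
    quasi-Bayesian causal mediation of expression by methylation, and a
    synthetic-data generator that plants all of the statistical structure
    the pipeline assumes, so that every stage can be validated against
    ground truth.
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
    glmnet,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    vcfR
Config/testthat/edition: 3
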