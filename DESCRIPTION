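Package: selindex
Title: Genomic Selection Indices and GBLUP Breeding Values for Working-Dog
    Breeding Programs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation, quality control, and genomic evaluation tools for
    small closed breeding populations such as guide-dog colonies. Provides a
    gene-dropping population simulator with liability-threshold binary and
    ordinal traits, PLINK-format genotype input/output, SNP and sample quality
    control (call rate, exact Hardy-Weinberg, minor allele frequency), VanRaden
    genomic relationship matrices with principal-component covariates,
    REML/GBLUP breeding-value estimation with arbitrary fixed effects,
    correlation-weighted multi-trait selection indices (Behavior, Health and
    Total Scores plus condition counts), and five-fold cross-validated
    predictive evaluation (MCC, AUROC, Kendall's tau, Spearman's rho,
    Pearson's R, NMSE, pseudo-heritability).
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
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
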