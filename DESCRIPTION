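Package: tidylocus
Title: Tidy Dissection of a GWAS Risk Locus: Association, eQTL, SMR-HEIDI
    and Allele-Specific Amplification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tidyverse-native toolkit for dissecting a single GWAS risk
    locus end to end: additive logistic association with subtype
    stratification, conditional and case-only analysis, fixed-effects
    inverse-variance meta-analysis with Cochran's Q, linkage-disequilibrium
    statistics (r-squared, D-prime) and proxy selection from phased
    haplotype panels, regulatory-interval annotation, latent-factor
    residualization of expression with cis-eQTL scanning, the summary-data
    Mendelian randomization (SMR) test for pleiotropy with the HEIDI
    heterogeneity filter, a binomial classifier of allele-specific
    amplification in trisomic tumors with reference-mapping-bias
    adjustment, and Pearson correlation with Fisher's method across
    studies. Ships a synthetic-data generator that emulates the
    statistical structure of a myeloma risk locus so every stage is
    testable without restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
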