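Package: neuroprs
Title: Polygenic Risk Scoring and Causal Brain-Structure Analysis for MCI-to-AD Conversion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline from GWAS summary statistics and
    cohort genotypes to a clumping-and-thresholding polygenic risk score,
    prediction of conversion from amnestic mild cognitive impairment to
    Alzheimer's disease (logistic regression with Nagelkerke pseudo-R-squared,
    ROC/AUC, Cox survival, stratified risk groups), a covariate-adjusted
    correlation scan of the score against regional brain measures with
    Benjamini-Hochberg FDR control, and a one-sample Mendelian randomization
    causal chain (score to regional surface area to conversion) by two-stage
    least squares. Includes genotype and sample quality control
    (Hardy-Weinberg exact test, relatedness by method-of-moments IBD,
    heterozygosity and call-rate filters, principal components) and a
    synthetic-cohort generator with LD-blocked genotypes so every stage is
    testable without restricted data.
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
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    survival,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
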