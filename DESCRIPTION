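Package: pcarisk
Title: Risk Stratification for Prostate Cancer from Genetic and
    Environmental Scores
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds and evaluates case-control risk stratification models
    that combine a polygenic genetic risk score (GRS), an environmental
    risk score (ERS) of modifiable factors, and family history.  Includes
    a synthetic case-control cohort simulator, variant quality control
    (Hardy-Weinberg filtering, LD r-squared pruning, genotype PCA),
    propensity-score-adjusted logistic modelling, decile stratification,
    discrimination metrics (AUROC with bootstrap optimism correction,
    continuous net reclassification improvement, integrated discrimination
    improvement), and projection of relative risks onto age-specific
    population incidence rates.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    vcfR
Config/testthat/edition: 3
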