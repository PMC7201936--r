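Package: lifecourseMR
Title: Life-Course Mendelian Randomisation for Early-Life and Adult Body Size
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Separates direct and adult-mediated effects of early-life body
    size on disease outcomes with two-sample univariable and multivariable
    Mendelian randomisation on GWAS summary statistics. Provides a synthetic
    cohort generator with tunable genetic architecture, linkage
    disequilibrium, mediation and confounding paths and self-report
    misclassification of the early-life measure; per-variant association
    scans for categorical and continuous phenotypes with covariate
    adjustment; a stacked variant-by-time interaction analysis with
    cluster-robust errors; greedy LD clumping; allele harmonization;
    inverse-variance-weighted, MR-Egger and multivariable MR estimators with
    Cochran's Q, F statistics and a direct/indirect effect decomposition; a
    negative-control design on age at menarche; genetic-score ROC
    validation; and a simulation study quantifying how exposure
    misclassification biases the multivariable estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pROC,
    sandwich,
    withr
Config/testthat/edition: 3
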