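Package: nmrconfound
Title: Confounder-Aware Multivariate Analysis of Untargeted Plasma NMR
    Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for untargeted plasma NMR metabolomics peak
    tables from multicenter cohorts: probabilistic quotient normalization,
    quality-control-based feature filtering, k-nearest-neighbour imputation
    and generalized-log variance stabilization; partial least squares
    discriminant analysis (dense and sparse) with VIP-based signature
    extraction under double cross-validation and Mahalanobis class
    prediction; and three complementary confounder-correction strategies
    (ANOVA-simultaneous-component-analysis residualization, exclusion of
    confounder-related peaks, and exclusion of compromised centers). A
    synthetic cohort generator emulates center clustering, preanalytical
    sample-age drift and batch structure so every stage is testable without
    patient data.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    mixOmics,
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
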