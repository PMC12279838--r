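Package: crossmir
Title: Cross-Omics Prediction of miRNA Expression Profiles from mRNA Data
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains multi-output deep neural networks and per-miRNA LASSO
    regression models that map mRNA expression profiles to miRNA expression
    profiles, and evaluates the predictions at the sample level and at the
    differential-expression level (concordance of log2 fold changes and raw
    p-values from an empirical-Bayes moderated t-test). Includes quantile
    normalization, a log-CPM transform for count data, global [0,1]
    compression, Gaussian-noise data augmentation for small cohorts,
    condition-specific model training, first-layer weight interpretation
    with transcription-factor enrichment, and a paired mRNA/miRNA simulator
    with known miRNA-to-target repression structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    jsonlite,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    limma,
    glmnet,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
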