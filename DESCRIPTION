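Package: emgselect
Title: Feature Extraction, Dimensionality Reduction and Exhaustive Feature
    Selection for Multi-Channel Surface EMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for movement classification from multi-channel
    surface electromyography (sEMG): seeded synthetic-signal generation,
    zero-phase notch/bandpass preprocessing, overlapping-window segmentation, a
    41-feature time- and frequency-domain catalog, single-feature ranking and
    elimination, six dimensionality-reduction / feature-selection methods (PCA,
    LDA, probabilistic PCA by EM, Gaussian process latent variable model,
    ReliefF, L1-penalized logistic regression), exhaustive feature-subset search
    with a feed-forward neural network under stratified 5-fold cross-validation,
    and one-way ANOVA comparison of feature-set sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
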