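Package: hoofgen
Title: Pedigree-Based Genetic Analysis of Angular Hoof Deviations
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Quantitative-genetic analysis of ordinal conformation defects in
    pedigreed horse populations. Provides pedigree parsing and validation,
    Wright's inbreeding coefficients by the Meuwissen-Luo algorithm, the
    numerator relationship matrix and its sparse inverse by Henderson's rules
    with the Quaas inbreeding correction, a Bayesian multi-trait threshold
    animal model estimated by Gibbs sampling (latent liabilities, inverse-
    Wishart covariance updates, deviance information criterion), post-Gibbs
    summaries and convergence diagnostics (highest posterior density
    intervals, Geweke Z, batch-means Monte Carlo standard errors,
    heritabilities, genetic correlations, breeding-value percentile overlap),
    descriptive prevalence and risk-factor screens, and a synthetic-data
    simulator with known genetic parameters for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    nnet,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
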