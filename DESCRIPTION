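Package: gxetradeoff
Title: Bias-Variance Decision Framework for Context-Specific Genetic Effect Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for choosing between additive (pooled) and context-specific
    (gene-by-environment, GxE) estimation of allelic effects on continuous
    traits. Implements single-locus stratified and pooled ordinary least
    squares, the weight identity relating the pooled estimator to the
    stratified estimators, the mean-squared-error decision rule and its
    dimensionless signal-to-noise form, a genome-wide screen of two-context
    GWAS summary statistics with LD-block resampling and data-splitting
    validation, Storey q-values, a gene-by-diet amplification simulator with
    top-hit classification, a lightweight empirical-Bayes multivariate
    shrinkage model (mixture of zero-centered normal priors fit by EM), and
    polygenic-score simulations comparing four ascertainment/estimation
    strategies under amplification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
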