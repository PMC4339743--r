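Package: mbensemble
Title: Ensemble Regression and Variable Selection for Microbiome Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Frequentist and Bayesian ensemble regression approaches for
    identifying taxa associated with a continuous outcome in high-dimensional
    microbiome studies. Implements stability-selection ensembles built on
    elastic-net regularization paths over subsamples or bootstrap resamples
    (with single-lambda, path-averaged and selection-weighted inclusion
    probabilities, and a per-family-error-controlled stable set), and
    spike-and-slab Bayesian model averaging via a Gibbs sampler with an
    optional cross-validated expected model size. Includes a seeded generator
    of microbiome-like count tables, construction of log relative-abundance
    design matrices with a reference taxon, signal-to-noise-calibrated
    response simulation, gap-based variable selection from inclusion
    probabilities, ROC/AUC, F-score and rank-correlation evaluation metrics,
    and a reproducible evaluation harness with checkpointing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite,
    parallel
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    pracma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
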