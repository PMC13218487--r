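Package: lexcal
Title: Calibration and Adequacy Testing for Bayesian Phylolinguistic Analyses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to validate and stress-test the standard Bayesian analysis of
    binarised cognate-coded lexical data. Implements the binary covarion
    substitution model with ascertainment-bias correction, simulation of
    cognate matrices on relaxed-clock Yule trees with weighted Dirichlet
    partition rates, Markov chain Monte Carlo inference over trees and model
    parameters, simulation-based calibration diagnostics (highest posterior
    density coverage, rank uniformity with ECDF difference bands, clade
    reliability diagrams), path-sampling marginal likelihoods with Bayes
    factor comparison of partition-rate weighting schemes, and posterior
    predictive checks of model adequacy for lexical evolution.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    Rcpp,
    jsonlite,
    ggplot2
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
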