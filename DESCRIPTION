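Package: lepdcm
Title: Dynamic Causal Modelling of Laser-Evoked Potential Habituation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale dynamic causal modelling (DCM) of laser-evoked
    potential (LEP) habituation in a thalamo-cortical pain network.
    Implements a convolution-based 'ERP' neural mass model over a
    seven-region network with a hidden thalamic source, a gain-matrix
    observation model, variational Laplace (free-energy) model inversion
    per subject, group-level parametric empirical Bayes with Bayesian
    model reduction and greedy search, scalp-level N2P2 habituation
    statistics with permutation tests, and a seeded synthetic two-group
    cohort generator so the full pipeline is testable without raw EEG.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
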