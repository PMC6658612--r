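Package: oxynet
Title: Signed Connectome Graph Metrics and Replicated Model Selection for
    Crossover Treatment Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for resting-state functional connectome studies
    of acute treatment response in a two-visit placebo-controlled crossover
    design. Builds signed, weighted, fully connected partial-correlation
    networks from ROI time series using analytic diagonal-target shrinkage of
    the covariance, computes eigenvector centrality and the signed weighted
    clustering coefficient per node, forms placebo-minus-drug difference
    scores, screens them against nuisance covariates with false-discovery-rate
    control, and associates node-level treatment response with clinical
    outcomes through a replicated best-subsets regression with held-out
    average-squared-error scoring, leave-one-out predictor importance,
    cumulative-importance selection and variance-inflation pruning. Includes a
    synthetic crossover cohort generator with planted treatment effects and
    outcome links so every stage is testable end to end without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    car,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
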