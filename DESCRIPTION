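Package: covertchoice
Title: Covert Pairwise Comparison Models of Sequential Option Sampling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation, fitting and comparison of value-updating choice
    models for sequential option sampling experiments, in which people
    browse through a set of rated items one at a time and finally select
    their favorite. Implements the full model family around the covert
    pairwise comparison ("bonus") model -- null softmax, primacy/recency
    biases, deterministic and probabilistic bonus updating, sequential
    pruning, saliency, and local/global/two-level carry-over variants --
    together with synthetic experiment-design generators, MAP estimation
    with Laplace-approximate model evidence, random-effects Bayesian model
    selection with exceedance probabilities, parameter and model recovery,
    and the model-free serial-position regression analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
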