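Package: curricsim
Title: Curriculum Learning Simulations for XOR Perceptual Decision Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates populations of parsimonious two-layer ReLU networks
    (K = 4 hidden units, no biases) learning an XOR Gaussian-mixture
    discrimination task by online stochastic gradient descent under four
    training curricula (ascending, hard, random, bad), including an exact
    reduced-coordinate engine that scales to arbitrary input dimension and a
    deterministic mean-field mode. Provides population statistics (pooled-SD
    Cohen's d, threshold achiever splits, binned training trajectories,
    pairwise logistic contrasts via iteratively reweighted least squares) and
    a synthetic random-dot-kinematogram study generator that emulates a
    matched four-arm human perceptual learning experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    lme4
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
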