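Package: pvrnn
Title: Variational Recurrent Networks with Adaptive Meta-Priors for
    Modeling Focus and Mind-Wandering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements a hierarchical predictive-coding variational
    recurrent neural network (PV-RNN) with deterministic multi-timescale
    units and Gaussian stochastic latents, trained by free-energy
    minimization with back-propagation through time. Includes a
    synthetic-data generator for probabilistically switching cyclic
    2-D patterns, sliding-window online inference (error regression)
    with frozen weights, an online meta-prior controller that switches
    the complexity weighting between a sensory-driven focus regime and
    a top-down mind-wandering regime in response to the recent average
    reconstruction error, and analysis tools for per-cycle pattern
    categorization, transition statistics and temperature sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
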