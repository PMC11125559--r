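Package: delayti
Title: Delay Transitive Inference in Trained Recurrent Networks
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how neural network models solve transitive
    inference (TI) across a working-memory delay. Implements task generation
    for delay and traditional 7-item TI, continuous-time recurrent neural
    networks (fully-, recurrent- and feedforward-trainable variants under
    five constraint regimes) trained by backpropagation through time,
    logistic-regression and multi-layer-perceptron baselines, noise-titrated
    behavioral simulation with the classical symbolic-distance, end-item and
    end-order indices, synthetic-subject generation for analysis-pipeline
    validation, and a population-dynamics and geometry suite: fixed points,
    linearization, least-squares linear dynamics, comparison-oscillation
    identification, collinearity-family indices, axis angles and encoding
    indices.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
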