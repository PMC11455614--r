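Package: thyrex
Title: Thyroid Hormone and Exploratory Behavior Analysis Toolkit
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis tools for studying how thyroid hormone
    (T3) shifts exploratory decision-making and cortical gene expression in
    mice. Implements a two-armed bandit (2ABT) task simulator with reversing
    reward contingencies, a four-parameter Q-learning choice model (learning
    rate, forgetting rate, inverse temperature, bias) with maximum-likelihood
    fitting and held-out evaluation, behavioral statistics (normalized reward
    rate, block-transition p(high) curves with exponential time constants,
    conditional switch probabilities), a pseudocell-based differential
    expression procedure with empirical-Bayes moderated t-statistics and
    robustness scoring for calling thyroid-responsive genes, syllable-stream
    entropy metrics, Hill-sigmoid fitting of optogenetic input-output curves,
    and seeded synthetic-data generators with ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    limma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
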