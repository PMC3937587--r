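Package: misclassim
Title: Monte Carlo Study of Classification with Mislabeled Training Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation framework for studying how systematic, boundary-proximal
    misclassification of training-group labels affects supervised classifiers in
    the three-group, single-predictor setting. Provides a calibrated label-noise
    injector (flip probability highest near artificial cut-points, expected flip
    fraction controlled by a closed-form scalar), eight classifiers behind a
    uniform fit/predict contract (linear and quadratic discriminant analysis,
    multinomial logistic regression, a deviance-splitting classification tree,
    a bootstrap-aggregated random forest of such trees, a penalized thin-plate
    spline additive model, a single-hidden-layer neural network, and mixture
    discriminant analysis fit by EM), misclassification-rate metrics, a fully
    crossed experiment runner with per-condition marginal summaries, and a
    repeated-measures analysis of variance screen with eta-squared effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    mgcv,
    nnet,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    randomForest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
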