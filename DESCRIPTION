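Package: crossyield
Title: Neural Collaborative Filtering for Inbred x Tester Cross-Yield
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts the yield of untested inbred x tester cross
    combinations in hybrid breeding programs by neural collaborative
    filtering: an ensemble of a generalized matrix factorization branch and
    a tower neural network over separate embedding layers, with planting
    location and genetic group as auxiliary inputs, trained by minibatch
    Adam on a Huber loss with optional two-stage embedding pre-training.
    Includes a sparse factorial cross-design simulator with known ground
    truth, reference baselines (constant mean, L1-penalized linear model,
    second-order factorization machines), cross-validation and
    hold-out-by-combination evaluation protocols, and decision-support
    analyses (full prediction matrix, heatmap export, marginal-yield
    categorization, embedding export).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    glmnet,
    Matrix,
    pheatmap,
    yaml,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
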