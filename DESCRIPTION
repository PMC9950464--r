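Package: abstractrep
Title: Abstract Representation Geometry in Multi-Task Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation framework for studying how abstract (disentangled)
    representations of continuous latent variables emerge in feedforward
    neural networks trained to perform many binary classification tasks.
    Provides generators for non-abstract input encodings of known latent
    variables (a participation-ratio-maximized autoencoder, Gaussian
    receptive fields, and frozen random Gaussian-process maps), families of
    classification tasks on the latents (linear, unbalanced, contextual,
    partial-information, grid, and Gaussian-process tasks), trainers for
    multi-task networks with masked targets (supervised and a single-step
    deep deterministic policy gradient variant), cross-condition
    generalization metrics of abstractness for any representation, and the
    analytic sign-covariance theory of representation dimensionality.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    glmnet,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
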