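Package: pvrnn
Title: Hierarchical Variational Recurrent Networks for Simulating Developmental Flexibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates developmental learning of hierarchical probabilistic
    structure with a predictive-coding-inspired variational recurrent neural
    network (PV-RNN). Provides a stochastic reaching-task environment with a
    hidden transition bias, a multiple-timescale three-layer network trained
    by meta-prior-weighted free-energy minimization, test-phase posterior
    inference by error regression, behavioral and cognitive flexibility
    metrics, latent-space traversal with a generative-hierarchy score, and an
    experiment grid with outlier filtering, ANOVA and Shaffer post-hoc tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    car,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
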