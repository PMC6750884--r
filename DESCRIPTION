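Package: twostagerl
Title: Simulation, Model Fitting and Choice Analysis for a Two-Stage
    Instrumental Decision Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying adaptive state-space and action-sequence
    representations in a two-stage instrumental decision task. Provides a
    generative simulator of the task (deterministic training contingencies,
    probabilistic probe transitions, unsignalled reward reversals), a set of
    reinforcement-learning agent families ranging from a flat single-stage
    learner to hierarchical model-based controllers with cached action
    sequences and latent sequence interruption, per-subject MAP fitting with
    Laplace-approximated model evidence and pseudo-r-squared, model and
    parameter recovery utilities, and the stay-probability mixed-effects
    logistic regression analyses that diagnose which controller generated
    the choices. A synthetic-cohort generator reproduces the statistical
    structure of the experimental design so the whole pipeline is testable
    without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    lme4,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
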