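Package: stroopdbn
Title: Discrete Dynamic Bayesian Network Models of Emotional-Stroop Behavior
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Fits competing cognitive models of implicit emotion regulation to
    emotional-Stroop trial sequences. Five discrete dynamic Bayesian networks
    (detector, attention, task-effort, threat-evaluation, conflict and
    categorical-layer accounts, with and without cross-trial feedback edges)
    are estimated by constrained multi-restart Baum-Welch expectation
    maximization, compared by AIC, AICc, HQC and BIC with relative
    likelihoods, and decoded by the Viterbi algorithm. Includes the
    emotional-Stroop task design (mixed block/event, factorial threat/neutral
    face-scene compounds), median-split response discretization, robust
    contrast-based task-validation statistics, a forward-sampling synthetic
    data generator with a reference parameter preset, and an
    amplitude-modulated general linear model linking decoded hidden-state
    timecourses to (synthetic) BOLD signal with group-level one-tailed tests
    and cluster-extent thresholding.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
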