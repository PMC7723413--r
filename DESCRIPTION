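Package: gazeglam
Title: Goal-Relevant Gaze-Weighted Accumulator Modelling of Choice and Confidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling binary choice, response time and confidence under
    goal framing with a gaze-weighted linear accumulator model (GLAM). Provides the
    goal-relevant evidence transforms for like/dislike and most/fewest task frames,
    an analytic Wald (inverse-Gaussian) race likelihood, stochastic path simulation
    with balance-of-evidence confidence, per-participant Bayesian (adaptive
    Metropolis) and MAP estimation with convergence diagnostics and WAIC model
    comparison, synthetic generators for value-based and perceptual eye-tracking
    experiments, two-stage behavioural regressions, a fixation time-series
    permutation test with FDR control, and a numerical verifier for the normative
    model of optimal information acquisition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    pracma,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
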