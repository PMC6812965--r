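Package: foxrabbit
Title: Model-Based and Stochastic Choice in Competitive Matching-Pennies Play
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of rule-based matching-pennies
    ("fox/rabbit") competitive games. Provides a closed-loop game simulator
    (simulated opponents with fixed switch rates, model-governed players,
    human-like dyads, action errors, feedback-locked synthetic signal
    epochs), a four-parameter feedback-contingent logistic choice model
    (model strength, loss-contingent model suppression, perseveration,
    win-stay/lose-shift) with condition-average least-squares and
    trial-by-trial maximum-likelihood estimation, reversed-label slope
    contrasts, multilevel choice-history and success regressions, and
    regression-based analyses of feedback-locked signals including a
    psychophysiological-interaction (PPI) step predicting upcoming choices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
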