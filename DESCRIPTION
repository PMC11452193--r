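Package: agtfit
Title: Effort-Based Decision-Making Models for Grip-Force Choice Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and hierarchical Bayesian analysis of effort-based
    decision-making data from Apple Gathering Task (AGT) style experiments,
    in which participants accept or refuse offers of reward (apples) in
    exchange for calibrated grip-force effort. Provides a seeded task and
    cohort simulator, a factorial family of subjective-value choice models
    (reward form x effort form x acceptance bias), hierarchical estimation
    with partial pooling (penalised-MAP and MCMC), model comparison via
    importance-sampling leave-one-out predictive density, posterior
    predictive checks, parameter-recovery studies, and the model-agnostic
    statistical arm: arcsine-transformed acceptance rates, mixed
    repeated-measures ANOVA with Greenhouse-Geisser correction, planned
    group contrasts with Cohen's d, design power via the noncentral F
    distribution, and parameter-symptom correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
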