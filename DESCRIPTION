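Package: moodrl
Title: Momentary Happiness and Reinforcement Learning in Stable and
    Volatile Bandit Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how momentary subjective well-being relates to
    reinforcement learning in a two-car "race" bandit with stable or volatile
    reward contingencies. Generates task schedules with exact 8-of-10 outcome
    blocks, simulates and fits Rescorla-Wagner learners with additive,
    multiplicative, probability-only and magnitude-only choice selectors by
    maximum likelihood, fits a family of eleven momentary-happiness models
    built from exponentially decaying histories of prediction errors,
    probability estimates, rewards and win/loss events, and compares models by
    summed BIC and random-effects Bayesian model selection (expected frequency
    and exceedance probability). A synthetic-cohort generator with cross-subject
    parameter heterogeneity and a symptom-mood coupling makes the full pipeline
    testable end to end, including parameter- and model-recovery reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    readr,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
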