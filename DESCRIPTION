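Package: somtrack
Title: Model-Based Analysis of Self-Other Mergence in Social Performance Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for social performance-tracking
    experiments in which participants rate their own and another player's
    ability under cooperative and competitive contexts. Provides a seeded
    generator for the crossed task design (feedback schedules, thresholds,
    rating-marker staircase), agents that track performance with a delta rule
    and carry a controllable context-signed self-other mergence (SOM) bias,
    group-level maximum-likelihood fitting of the Rescorla-Wagner/softmax
    choice model, trial-wise logistic rating GLMs that quantify SOM as
    performance-by-context interactions, and the group-level tests (baseline
    one-sample t tests, mixed-design ANOVA for a stimulation manipulation)
    applied to the resulting per-session effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    purrr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
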