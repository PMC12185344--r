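Package: moodgamble
Title: Risk-Taking Adaptation and Mood in Longitudinal Gamble-Task Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of longitudinal two-option gamble
    ("wheel of fortune") experiments used to study risk taking in bipolar
    disorder and bipolar-risk cohorts. Implements the utility/softmax choice
    model with outcome-history modulation of loss sensitivity, per-session
    Bayesian parameter estimation (Metropolis MCMC or MAP plus Laplace),
    parameter-recovery and cross-validated model-comparison harnesses,
    model-free behavioural statistics (choice curves, win/loss dimension
    sensitivity, outcome-history contrasts), hierarchical location-scale
    regressions with ordered-factor ("bipolar gradient") and drug-by-time
    contrasts, and mood analyses (instability, happiness-outcome coupling,
    mood-noisiness coupling). Includes a synthetic-cohort generator that
    emulates the task's near-equal-expected-value stimulus design and a
    reproducible end-to-end pipeline.
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
    jsonlite,
    numDeriv,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
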