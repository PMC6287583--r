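Package: saccadecd
Title: Corollary-Discharge Gain Analysis for Double-Saccade Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying corollary-discharge (efference copy) signals
    with the double-saccade paradigm. Provides a generative model of
    two-saccade trials with an explicit corollary-discharge gain, screen and
    task geometry helpers, fixation-table preprocessing (trial screening,
    closest-fixation matching, canonical transposition, signed endpoint
    errors), trial-by-trial compensation statistics (ideal versus actual
    second-saccade angle and amplitude), a QUEST adaptive Bayesian staircase
    for 2AFC contrast thresholds and saccadic-suppression analysis, dopamine
    transporter SPECT specific-binding-ratio covariates, and linear
    mixed-effects inference with marginality-respecting model pruning and
    cluster bootstrap confidence intervals. Synthetic cohorts make the whole
    pipeline runnable end to end without external data.
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
    lme4,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
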