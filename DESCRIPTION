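Package: oncostm
Title: Partitioned Survival and Multi-State Cohort Models for Oncology
    Treatment Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares partitioned survival modelling with 3-state and
    5-state semi-Markov cohort modelling for second-line treatment of
    EGFR-mutated advanced non-small cell lung cancer, where the 5-state
    structure adds brain-metastasis health states with reduced utility.
    Provides a synthetic claims-like patient-level data generator with
    competing latent event times, endpoint derivation and greedy 1:1
    propensity matching, parametric survival extrapolation over six
    families with information-criterion model selection, cohort trace
    engines with time-in-state tunnel states and time-dependent
    transition probabilities, an individual-level microsimulation
    oracle, and discounted life-year and quality-adjusted life-year
    summaries with one-way sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    flexsurv,
    graphics,
    jsonlite,
    stats,
    survival,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
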