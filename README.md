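# oncostm

Structural uncertainty in oncology cost-effectiveness models: does it
matter whether you build a partitioned survival model (PSM), a 3-state
cohort model, or a 5-state cohort model with explicit brain-metastasis
states? `oncostm` implements all three for the same decision problem —
second-line therapy in EGFR-mutated advanced NSCLC, an osimertinib-like
arm (A) versus pemetrexed–platinum chemotherapy (B) — and compares their
discounted incremental life-year (LY) and QALY estimates.

The core finding the package reproduces: the three structures agree
closely on incremental LY, but the 5-state model reports a much lower
incremental QALY, because time that the CNS-active arm spends with brain
metastases *while continuing initial therapy* counts as progression-free
(utility 0.800) in the PSM and 3-state model but is re-weighted to the
brain-metastasis utilities (0.520/0.478) in the 5-state model.

## What is inside

* **Synthetic claims-like cohort generator** (`sim_config()`,
  `generate_cohorts()`, `emit_claims()`): a five-state semi-Markov
  disease course (progression-free, post-progression, brain metastasis
  with continuing/subsequent therapy, death) simulated by competing
  cause-specific latent times with clocks restarting at state entry;
  administrative censoring; a claims-based diagnosis rule (≥1 inpatient
  or ≥2 outpatient C793 claims, `diagnose_brain_metastasis()`); greedy
  1:1 propensity matching on age and sex (`propensity_match()`).
* **Survival layer** (`km_estimate()`, `fit_parametric()`,
  `select_best()`, `test_proportional_hazards()`): Kaplan–Meier,
  right-censored maximum likelihood for six parametric families
  (exponential, Weibull, Gompertz, lognormal, log-logistic, generalized
  gamma) via flexsurv, AIC/AICc/BIC selection, PH diagnostics.
* **Cohort engines** (`build_psm_trace()`, `build_stm3_trace()`,
  `build_stm5_trace()`): curve-partitioned PSM; semi-Markov cohort
  engines with time-dependent transition probabilities
  `1 − S(t+c)/S(t)`, tunnel states tracking time-in-state to full
  horizon depth, and a hazard-proportional competing-exit rule; plus an
  individual-level microsimulation oracle (`microsimulate()`).
* **Outcomes** (`summarize_outcomes()`, `compare_structures()`,
  `sensitivity_grid()`): trapezoidal, continuously discounted LY/QALY by
  health state, incremental comparisons, one-way sensitivity analysis.
* **Orchestration** (`run_study()`): the full pipeline under one config
  and one seed, with a run manifest logging selected families and every
  floor/cap/non-convergence event.

The `analysis/` directory holds the study as numbered stages
(`01_simulate_cohorts.R` … `06_figures.R`), each a thin driver over the
package that reads and writes plain-text artifacts under `results/`, so
any stage can be re-run from disk.

## Worked example

```r
library(oncostm)
res <- run_study(default_study_config(seed = 1), sensitivity = FALSE)
it <- incremental_table(res)
it[it$state == "total", ]
#>   structure state inc_ly inc_qaly
#> 1       PSM total  0.808    0.729
#> 4      STM3 total  0.795    0.721
#> 7      STM5 total  0.810    0.556
```

735 matched patients per arm are synthesized, twelve time-to-event
endpoints derived, six parametric families fitted to each endpoint per
arm and the best AIC fit selected, and the three structures traced over
7 years in 21-day cycles at a 4.5% annual discount. Incremental LY
(arm A − arm B) agrees across structures within about 2% here
(0.795–0.810 discounted years gained), while the 5-state structure's
incremental QALY (0.556) sits 23–24% below the PSM and 3-state values
(0.729/0.721) — the brain-metastasis re-weighting:

```r
res$comparison[res$comparison$structure == "STM5" &
               res$comparison$metric == "qaly", ]
#>    structure reference metric     value ref_value rel_diff_pct
#> 10      STM5       PSM   qaly 0.5563516 0.7294479          -24
#> 12      STM5      STM3   qaly 0.5563516 0.7210060          -23
```

Per-state splits (`incremental_table(res)`), fitted-family selections
(`res$manifest$selected_families`) and sensitivity analyses
(`run_study(..., sensitivity = TRUE)$sensitivity`) come with the result.

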