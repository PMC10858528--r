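---
title: "Comparing partitioned survival and multi-state cohort models with brain-metastasis states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing partitioned survival and multi-state cohort models with brain-metastasis states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question

Cost-effectiveness models for oncology drugs usually take one of two
shapes. A *partitioned survival model* (PSM) reads state occupancy
directly off extrapolated survival curves: dead is one minus overall
survival (OS), progression-free (PF) is the progression-free-survival
proxy curve, and post-progression (PP) is the gap between the two. A
*state transition model* (STM) instead propagates a cohort through
mutually exclusive health states with per-cycle transition
probabilities. The choice matters most when the disease has clinically
heterogeneous phases that the three-state collapse hides.

Second-line treatment of EGFR-mutated advanced NSCLC is such a case.
Patients on a CNS-active agent (arm "A" here, an osimertinib-like
therapy) often develop brain metastases yet *continue* their initial
therapy; in a three-state model that time is indistinguishable from
progression-free time, although its quality of life is much lower. This
package builds the same decision problem three ways — PSM, a 3-state STM
(PF, PP, death) and a 5-state STM that adds *brain metastasis with
continuing initial therapy* (BMIT) and *with subsequent therapy*
(BMST) — and compares discounted incremental life-years (LY) and
quality-adjusted life-years (QALY) between the two treatment arms.

The headline structural phenomenon the package reproduces: the three
structures agree closely on incremental LY, while the 5-state model
reports a markedly lower incremental QALY, because arm A's long
brain-metastasis sojourns are re-weighted from PF utility (0.800) down
to BMIT/BMST utility (0.520/0.478).

## Synthetic claims-like data

Real claims data of this kind are not shareable, so the package ships a
generator (`sim_config()`, `generate_cohorts()`) that emulates the
extraction from a national claims database:

* Two arms of 735 patients (the matched cohort size), 61.5% female,
  age 64.9 (SD 9.3) years, accrued uniformly over three years with an
  administrative cut-off two years after accrual ends (days 0–1095 and
  1825 from the accrual origin). Follow-up is therefore 2–5 years while
  the model horizon is 7 years: extrapolation is a genuine part of the
  problem, as it is in practice.
* A five-state semi-Markov disease course. On entry to each state a
  latent time is drawn for every outgoing edge from a cause-specific
  hazard (exponential or Weibull per edge); the minimum wins, and
  clocks restart at state entry. Ties route brain metastasis before
  progression (a deterministic tie-break; ties have probability zero
  under continuous times).
* 25% of patients have a brain-metastasis history at index and start in
  BMIT.
* Brain metastasis becomes *observable* only through claims: a
  qualifying pattern (one inpatient claim, or two outpatient claims 14
  days apart, ICD-10 C793) is emitted at onset (configurable lag,
  default 0), and 5% of never-BM patients carry a single non-qualifying
  outpatient claim as noise. The diagnosis rule — at least one inpatient
  or two outpatient claims, diagnosis date the first date the rule is
  satisfied — is `diagnose_brain_metastasis()`.

Default hazards were chosen once to mirror the published magnitudes:
arm A median time-to-next-treatment about 16 months and mean OS about 3
years versus roughly 6 months and 1.5 years for arm B, with arm A's
BMIT/BMST exit hazards substantially lower (the CNS-active drug keeps
controlling intracranial disease, so patients persist in the
brain-metastasis states). The generator emulates covariate balance,
administrative censoring and the claims-based diagnosis rule; it does
*not* emulate measurement error in death dates, time-varying hazards
beyond Weibull shape, informative censoring, or covariate-dependent
risks. Passing tests therefore demonstrate internal consistency of the
modeling machinery under a plausible data-generating process, not
validity on any particular real dataset.

## Endpoints

`derive_endpoint_datasets()` reconstructs each patient's *observed* path
from the therapy-switch date, the claims-derived diagnosis date (not the
latent onset) and death, censors at the cut-off, and emits twelve
right-censored datasets: OS; TTNT (time to next treatment or death, the
PFS proxy); death before/after the therapy switch (`death_from_pf`,
`death_from_pp`, from index and from the switch respectively); the
5-state cause-specific curves `ttnt_from_pf`, `bm_from_pf`,
`bm_from_pp`, `ttnt_in_bmit`, `death_in_bmit`, `death_in_bmst`; and two
BM-free refinements `death_from_pf_bmfree` / `death_from_pp_bmfree`
(censored at brain-metastasis entry).

Why both death-curve flavours? The 3-state model's death transitions
must describe *all* pre-switch and post-switch mortality, including the
patients who are in a brain-metastasis state that the 3-state view
cannot see; its PF occupancy is anchored exactly by the TTNT total-exit
curve, so only that overall composition matters. The 5-state model, by
contrast, applies separate death hazards inside BMIT and BMST, so its PF
and PP death curves must be estimated on the BM-free risk sets —
otherwise brain-metastasis mortality is counted twice and the 5-state
model systematically under-predicts survival. Estimating every
transition hazard on its own risk set is the standard cause-specific
construction for multistate models, and it is what makes the three
structures agree on incremental LY while disagreeing on QALY for the
right reason.

## Survival fitting and selection

Each endpoint is fitted per arm by right-censored maximum likelihood
(`fit_parametric()`, via flexsurv) for six families: exponential,
Weibull, Gompertz, lognormal, log-logistic and generalized gamma (in the
(μ, σ, Q) parameterization, whose Q = 1 and Q → 0 limits recover the
Weibull and lognormal — a nesting the tests exploit). AIC, AICc
(`AIC + 2k(k+1)/(n−k−1)`, n = subjects) and BIC (`k·ln n − 2ℓ`) are all
reported; selection defaults to lowest AIC with ties broken by fewer
parameters and then a fixed family order, because a reproducible
pipeline needs a deterministic rule. An explicit per-curve override
stands in for the visual inspection a human modeller would add.
Non-converged fits (flagged, never fatal) are excluded from selection;
generalized gamma and Gompertz retry from moment-style starting values.
Proportional-hazards diagnostics (`test_proportional_hazards()`:
log-cumulative-hazard curves, scaled Schoenfeld residuals, global test)
are reported for description only — all endpoints are modelled
independently per arm, so no shared-coefficient models are fitted.

## The three engines

All engines use a 21-day cycle (the comparator's administration
interval) and a 7-year horizon — 122 cycles, with occupancy recorded at
cycle boundaries. Sensitivity analyses rebuild at 5 and 10 years (87 and
174 cycles).

**PSM** (`build_psm_trace()`): death `1 − S_OS(t)`, PF
`min(S_TTNT(t), S_OS(t))` — the cap keeps PP non-negative where fitted
curves cross, and cap activations are counted in the trace's event log —
and PP the remainder.

**Semi-Markov engines** (`build_stm3_trace()`, `build_stm5_trace()`).
The central primitive is the conditional one-cycle exit probability
`1 − S(t+c)/S(t)`, evaluated on the *model-time* clock for PF (entered
at time zero, so the clocks coincide) and on the *time-in-state* clock
for PP, BMIT and BMST. Time-in-state dependence is realized by tunnel
layers: each tunnel state keeps one occupancy slot per completed cycle
in state, to the full horizon depth (no truncation — exactness is cheap
at this scale); entrants start at layer zero the following cycle.

Competing exits are combined by a constant-cause-specific-hazard rule:
each cause's conditional probability is converted to a cycle hazard
`λᵢ = −ln(1−qᵢ)/c`, the total exit is `1 − exp(−cΣλᵢ)`, and it is
allocated in proportion to the hazards. This guarantees probabilities
summing to at most one for any driving curves, reduces to `qᵢ` for a
single cause, and makes a zero-hazard cause drop out exactly — which is
what lets the 5-state engine collapse onto the 3-state engine to
machine precision when the brain-metastasis hazards vanish. The
3-state PF state has no progression-only curve; its progression
probability is backed out of the TTNT total-exit curve by
`q_prog = 1 − (1 − q_ttnt)/(1 − q_death)` (floored at zero and counted
when the independently fitted curves disagree), so total PF exit equals
the TTNT curve's prediction exactly. A literal
subtract-the-probabilities variant is available as
`competing = "subtraction"`; the two differ at second order in the
cycle length. When a conditional probability reaches one, the entire
exit goes to that cause.

Verification is dual-route throughout: with all-exponential curves the
engines must match a time-homogeneous matrix-power solution to 1e-8,
and for arbitrary structures an individual-level microsimulation
(`microsimulate()`, sharing the engines' per-cycle probabilities and
clocks verbatim) must agree within binomial error at 200,000
individuals. Conservation (rows summing to one within 1e-9, monotone
death, non-negative occupancy, tunnel layers summing to their state) is
asserted over randomized curve sets.

## Outcomes

`summarize_outcomes()` integrates occupancy by the trapezoid on the
cycle grid — equivalent to a half-cycle correction, applied uniformly so
the PSM/STM comparison is on equal footing — weighting by
`(1 + r)^(−t/365.25)` inside the integrand (continuous-time
discounting; at 21-day cycles it differs from a per-cycle step factor by
under 0.05% and has a closed-form annuity oracle). Default annual rate
4.5%. Utilities: PF 0.800/0.730 (arm A/B), BMIT 0.520 shared, with a
0.042 progression decrement giving PP 0.758/0.688 and BMST 0.478; they
are time-constant within a state and age-independent. Death contributes
nothing. Incrementals are arm A minus arm B; `compare_structures()`
reports pairwise relative differences rounded half-away-from-zero to
integer percent, with a zero reference reported as undefined rather
than infinite.

One-way sensitivity (`sensitivity_grid()`) varies horizon (5, 10
years), discount rate (3%, 7.5%) and named alternative utility sets,
one dimension at a time from the base case.

## Numerical and design choices worth knowing

* Days are the internal unit everywhere; one year is 365.25 days.
* Matching: logistic propensity on age and sex, greedy 1:1 nearest
  neighbour on the logit scale processing arm-A patients in descending
  score order without replacement; optional caliper in units of
  SD(logit), off by default. Standardized mean differences use the
  pooled-SD form; degenerate covariates report zero with a warning.
* Endpoints with empty risk sets warn and return empty datasets; in the
  orchestrated study an endpoint–arm with no events is driven by a
  degenerate zero-rate exponential (the transition the data never
  exhibit), logged in the run manifest.
* All floor/cap/non-convergence events are counted and surfaced in the
  manifest, because the structural comparison is only interpretable
  when curve-inconsistency corrections are visible.
* One master seed fans out to stage-specific seeds (data, claims), so
  changing a downstream stage never perturbs data generation;
  `run_study()` is bit-reproducible given the seed.
* Test problem sizes: conservation over 100 random curve sets,
  microsimulation oracles at 50,000–200,000 individuals, parameter
  recovery at n = 2,000 with 20% administrative censoring over 20
  replicates, selection consistency at n = 1,000 over 15 replicates.

## Limitations

Costs and incremental cost-effectiveness ratios are out of scope, as is
probabilistic sensitivity analysis. The generator's hazards are
population-level and covariate-free, so propensity matching exercises
balance machinery rather than confounding control. Incremental LY
agreement across structures is a property of correctly specified,
consistently estimated curves: with flexible families selected by AIC on
heavily censored cause-specific endpoints, individual seeds can still
produce extrapolation tails that push the spread to several percent —
the run manifest's selection table and floor counts are the first place
to look when that happens.
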