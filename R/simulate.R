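#' Configuration for the synthetic claims-like cohort generator
#'
#' Defines the study conditions emulated by the generator: two treatment
#' arms ("A", osimertinib-like; "B", pemetrexed-platinum-like) of
#' second-line EGFR-mutated advanced NSCLC patients, followed from a
#' treatment-switch index date through a five-state disease course --
#' progression-free (PF), post-progression (PP), brain metastasis with
#' continuing initial therapy (BMIT), brain metastasis with subsequent
#' therapy (BMST), and death -- under administrative censoring at a study
#' cut-off.
#'
#' Event generation is semi-Markov: on entry to each state a latent time
#' is drawn for every outgoing edge from a cause-specific hazard
#' (exponential or Weibull by default; any registered family is allowed),
#' clocks restart at state entry, and the minimum latent time decides the
#' transition taken. Patients with a brain-metastasis history at index
#' (`baseline_bm_fraction`) start in BMIT.
#'
#' Default hazards were chosen to mirror the published magnitudes for
#' this population: arm A with median time-to-next-treatment around 16
#' months and mean overall survival around 3 years, arm B around 6 months
#' and 1.5 years, and substantially longer brain-metastasis-state
#' sojourns in arm A (the CNS-active drug is continued after brain
#' metastasis, so exit hazards from BMIT/BMST are lower).
#'
#' @param n_per_arm Patients per arm (default 735, the matched cohort
#'   size of the motivating study).
#' @param seed Integer seed controlling all randomness in
#'   [generate_cohorts()].
#' @param study_cutoff Administrative cut-off in days from the earliest
#'   possible index date.
#' @param index_dispersion Accrual window: index dates are uniform on
#'   `[0, index_dispersion]` days.
#' @param female_fraction,age_mean,age_sd Baseline covariate spec
#'   (defaults 0.615, 64.9 y, 9.3 y).
#' @param age_shift_b Mean-age shift (years) applied to arm B, to create
#'   covariate imbalance for matching exercises; default 0 (balanced).
#' @param baseline_bm_fraction Probability of brain-metastasis history at
#'   index (model starts in BMIT).
#' @param hazards Nested list `hazards$A$pf_pp`, ... with one
#'   `list(family=, params=)` spec per edge and arm; edges are `pf_pp`,
#'   `pf_death`, `pf_bm`, `pp_death`, `pp_bm`, `bmit_ttnt`, `bmit_death`,
#'   `bmst_death`.
#' @param bm_claim_lag Days between (latent) brain-metastasis onset and
#'   the first qualifying claim (default 0).
#' @param claim_noise_fraction Fraction of never-brain-metastasis
#'   patients who receive a single, non-qualifying outpatient C793 claim.
#' @param inpatient_claim_prob Probability that a true brain metastasis
#'   is documented by one inpatient claim rather than two outpatient
#'   claims.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_per_arm = 735L,
                       seed = 1L,
                       study_cutoff = 1825,
                       index_dispersion = 1095,
                       female_fraction = 0.615,
                       age_mean = 64.9,
                       age_sd = 9.3,
                       age_shift_b = 0,
                       baseline_bm_fraction = 0.25,
                       hazards = default_hazards(),
                       bm_claim_lag = 0,
                       claim_noise_fraction = 0.05,
                       inpatient_claim_prob = 0.6) {
  stopifnot(n_per_arm >= 1, study_cutoff >= index_dispersion,
            index_dispersion >= 0, age_sd > 0, bm_claim_lag >= 0)
  for (p in c(female_fraction, baseline_bm_fraction, claim_noise_fraction,
              inpatient_claim_prob)) {
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  edges <- c("pf_pp", "pf_death", "pf_bm", "pp_death", "pp_bm",
             "bmit_ttnt", "bmit_death", "bmst_death")
  for (arm in c("A", "B")) {
    if (is.null(hazards[[arm]])) stop(sprintf("missing hazards for arm %s", arm), call. = FALSE)
    for (e in edges) {
      hazards[[arm]][[e]] <- validate_hazard_spec(hazards[[arm]][[e]],
                                                  paste(arm, e, sep = ":"))
    }
  }
  structure(list(n_per_arm = as.integer(n_per_arm), seed = as.integer(seed),
                 study_cutoff = study_cutoff, index_dispersion = index_dispersion,
                 female_fraction = female_fraction, age_mean = age_mean,
                 age_sd = age_sd, age_shift_b = age_shift_b,
                 baseline_bm_fraction = baseline_bm_fraction,
                 hazards = hazards, bm_claim_lag = bm_claim_lag,
                 claim_noise_fraction = claim_noise_fraction,
                 inpatient_claim_prob = inpatient_claim_prob),
            class = "sim_config")
}

#' Default per-edge cause-specific hazards
#'
#' Time unit is days. See [sim_config()] for the rationale behind the
#' magnitudes.
#' @return Nested list of hazard specs by arm and edge.
#' @export
default_hazards <- function() {
  exp_ <- function(rate) list(family = "exponential", params = c(rate = rate))
  wei <- function(shape, scale) list(family = "weibull",
                                     params = c(shape = shape, scale = scale))
  list(
    A = list(
      pf_pp = wei(1.2, 700), pf_death = exp_(1 / 2500), pf_bm = exp_(1 / 1200),
      pp_death = wei(1.1, 600), pp_bm = exp_(1 / 900),
      bmit_ttnt = exp_(1 / 700), bmit_death = exp_(1 / 1100),
      bmst_death = wei(1.1, 450)
    ),
    B = list(
      pf_pp = wei(1.2, 260), pf_death = exp_(1 / 1400), pf_bm = exp_(1 / 1000),
      pp_death = wei(1.1, 420), pp_bm = exp_(1 / 700),
      bmit_ttnt = exp_(1 / 250), bmit_death = exp_(1 / 500),
      bmst_death = wei(1.1, 300)
    )
  )
}

# competing transition out of a state: returns list(time, dest index)
# with deterministic tie-break priority = order of the `times` list.
.take_min <- function(times) {
  m <- do.call(pmin, times)
  dest <- rep(NA_integer_, length(m))
  for (j in rev(seq_along(times))) dest[times[[j]] <= m] <- j
  list(time = m, dest = dest)
}

#' Generate the synthetic two-arm patient cohort
#'
#' Draws baseline covariates and simulates each patient's full latent
#' disease path through the five-state graph (PF -> PP/BMIT/Death,
#' PP -> BMST/Death, BMIT -> BMST/Death, BMST -> Death) by competing
#' cause-specific latent times with clocks restarting at state entry.
#' Where latent brain-metastasis and next-treatment times tie, brain
#' metastasis takes precedence. Paths are simulated to death (or to a
#' state with no active exits); censoring is applied later, at endpoint
#' derivation, so a higher cut-off reveals more events.
#'
#' @param config A [sim_config()].
#' @return A data frame (one row per patient, class `patient_cohort`)
#'   with covariates, absolute state-entry times in days from index
#'   (`t_pp_entry`, `t_bmit_entry`, `t_bmst_entry`, `t_death`; `NA` if
#'   the state is never reached) and the per-state latent draws.
#' @export
generate_cohorts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_per_arm
  out <- list()
  for (arm in c("A", "B")) {
    hz <- config$hazards[[arm]]
    age_mu <- config$age_mean + if (arm == "B") config$age_shift_b else 0
    d <- data.frame(
      id = paste0(arm, seq_len(n)),
      arm = arm,
      index_date = stats::runif(n, 0, config$index_dispersion),
      female = stats::rbinom(n, 1, config$female_fraction) == 1,
      age = stats::rnorm(n, age_mu, config$age_sd),
      baseline_bm = stats::rbinom(n, 1, config$baseline_bm_fraction) == 1
    )
    d$t_pp_entry <- NA_real_
    d$t_bmit_entry <- NA_real_
    d$t_bmst_entry <- NA_real_
    d$t_death <- NA_real_
    lat <- c("lat_pf_pp", "lat_pf_death", "lat_pf_bm", "lat_pp_death",
             "lat_pp_bm", "lat_bmit_ttnt", "lat_bmit_death", "lat_bmst_death")
    for (v in lat) d[[v]] <- NA_real_

    # stage 1: PF (everyone without baseline brain metastasis)
    pf <- which(!d$baseline_bm)
    d$t_bmit_entry[d$baseline_bm] <- 0
    if (length(pf)) {
      t_bm <- rsurv(length(pf), hz$pf_bm)
      t_pp <- rsurv(length(pf), hz$pf_pp)
      t_de <- rsurv(length(pf), hz$pf_death)
      d$lat_pf_bm[pf] <- t_bm; d$lat_pf_pp[pf] <- t_pp; d$lat_pf_death[pf] <- t_de
      # priority on ties: BM, then progression, then death
      mv <- .take_min(list(t_bm, t_pp, t_de))
      fin <- is.finite(mv$time)
      d$t_bmit_entry[pf[fin & mv$dest == 1]] <- mv$time[fin & mv$dest == 1]
      d$t_pp_entry[pf[fin & mv$dest == 2]] <- mv$time[fin & mv$dest == 2]
      d$t_death[pf[fin & mv$dest == 3]] <- mv$time[fin & mv$dest == 3]
    }

    # stage 2: PP entrants
    pp <- which(!is.na(d$t_pp_entry))
    if (length(pp)) {
      t_bm <- rsurv(length(pp), hz$pp_bm)
      t_de <- rsurv(length(pp), hz$pp_death)
      d$lat_pp_bm[pp] <- t_bm; d$lat_pp_death[pp] <- t_de
      mv <- .take_min(list(t_bm, t_de))
      fin <- is.finite(mv$time)
      i <- pp[fin & mv$dest == 1]
      d$t_bmst_entry[i] <- d$t_pp_entry[i] + mv$time[fin & mv$dest == 1]
      i <- pp[fin & mv$dest == 2]
      d$t_death[i] <- d$t_pp_entry[i] + mv$time[fin & mv$dest == 2]
    }

    # stage 3: BMIT entrants (baseline BM starters plus PF -> BMIT)
    bmit <- which(!is.na(d$t_bmit_entry))
    if (length(bmit)) {
      t_nt <- rsurv(length(bmit), hz$bmit_ttnt)
      t_de <- rsurv(length(bmit), hz$bmit_death)
      d$lat_bmit_ttnt[bmit] <- t_nt; d$lat_bmit_death[bmit] <- t_de
      mv <- .take_min(list(t_nt, t_de))
      fin <- is.finite(mv$time)
      i <- bmit[fin & mv$dest == 1]
      d$t_bmst_entry[i] <- d$t_bmit_entry[i] + mv$time[fin & mv$dest == 1]
      i <- bmit[fin & mv$dest == 2]
      d$t_death[i] <- d$t_bmit_entry[i] + mv$time[fin & mv$dest == 2]
    }

    # stage 4: BMST entrants
    bmst <- which(!is.na(d$t_bmst_entry))
    if (length(bmst)) {
      t_de <- rsurv(length(bmst), hz$bmst_death)
      d$lat_bmst_death[bmst] <- t_de
      fin <- is.finite(t_de)
      d$t_death[bmst[fin]] <- d$t_bmst_entry[bmst[fin]] + t_de[fin]
    }
    out[[arm]] <- d
  }
  res <- rbind(out$A, out$B)
  rownames(res) <- NULL
  attr(res, "config") <- config
  class(res) <- c("patient_cohort", "data.frame")
  res
}

#' Censoring time (days from index) for each patient
#' @param records A `patient_cohort`.
#' @param cutoff Study cut-off in days from the accrual origin; defaults
#'   to the generating config's cut-off.
#' @return Numeric vector, `cutoff - index_date`.
#' @export
censor_time <- function(records, cutoff = NULL) {
  if (is.null(cutoff)) cutoff <- attr(records, "config")$study_cutoff
  cutoff - records$index_date
}

#' Emit C793 diagnosis claims for the synthetic cohort
#'
#' Patients whose path reaches a brain-metastasis state within follow-up
#' receive a qualifying claim pattern (one inpatient claim, or two
#' outpatient claims two weeks apart) starting `bm_claim_lag` days after
#' onset; a configurable fraction of never-brain-metastasis patients
#' receive exactly one outpatient claim, which does not satisfy the
#' diagnosis rule.
#'
#' @param records A `patient_cohort`.
#' @param config The generating [sim_config()] (defaults to the one
#'   attached to `records`).
#' @param claims_seed Seed for claim-pattern randomness, separate from
#'   the cohort seed so the data stage is unaffected.
#' @return Data frame with `id`, `service_date` (days from the patient's
#'   index date), `setting` (`"inpatient"`/`"outpatient"`), `code`.
#' @export
emit_claims <- function(records, config = attr(records, "config"),
                        claims_seed = config$seed + 1L) {
  stopifnot(inherits(records, "patient_cohort"))
  set.seed(claims_seed)
  cens <- censor_time(records, config$study_cutoff)
  # first BM onset: BMIT entry, or BMST entry when BM arose from PP
  bm_onset <- ifelse(!is.na(records$t_bmit_entry), records$t_bmit_entry,
                     ifelse(!is.na(records$t_pp_entry) & !is.na(records$t_bmst_entry),
                            records$t_bmst_entry, NA_real_))
  claim_t <- bm_onset + config$bm_claim_lag
  death_t <- ifelse(is.na(records$t_death), Inf, records$t_death)
  obs <- !is.na(claim_t) & claim_t <= pmin(cens, death_t)
  rows <- list()
  idx <- which(obs)
  if (length(idx)) {
    inpat <- stats::runif(length(idx)) < config$inpatient_claim_prob
    # baseline-BM history is documented at index by an inpatient claim
    inpat[records$baseline_bm[idx]] <- TRUE
    i1 <- idx[inpat]
    rows[[length(rows) + 1L]] <- data.frame(
      id = records$id[i1], service_date = claim_t[i1], setting = "inpatient",
      code = "C793")
    i2 <- idx[!inpat]
    if (length(i2)) {
      second <- pmin(claim_t[i2] + 14, cens[i2])
      rows[[length(rows) + 1L]] <- data.frame(
        id = rep(records$id[i2], 2L),
        service_date = c(claim_t[i2], second),
        setting = "outpatient", code = "C793")
    }
  }
  never <- which(is.na(bm_onset))
  if (length(never) && config$claim_noise_fraction > 0) {
    noisy <- never[stats::runif(length(never)) < config$claim_noise_fraction]
    if (length(noisy)) {
      fu <- pmin(ifelse(is.na(records$t_death[noisy]), Inf, records$t_death[noisy]),
                 cens[noisy])
      rows[[length(rows) + 1L]] <- data.frame(
        id = records$id[noisy],
        service_date = stats::runif(length(noisy), 0, pmax(fu, 1e-6)),
        setting = "outpatient", code = "C793")
    }
  }
  claims <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(), service_date = numeric(),
               setting = character(), code = character())
  claims <- claims[order(claims$id, claims$service_date), , drop = FALSE]
  rownames(claims) <- NULL
  claims
}

#' Apply the claims-based brain-metastasis diagnosis rule
#'
#' A patient is diagnosed with brain metastasis if they have at least one
#' inpatient claim or at least two outpatient claims with ICD-10 code
#' C793. The diagnosis date is the first date at which the rule is
#' satisfied: the earliest inpatient claim date or the second outpatient
#' claim date, whichever comes first.
#'
#' @param claims Claims for a single patient (data frame with
#'   `service_date`, `setting`, `code`).
#' @return `list(bm = flag, date = diagnosis date or NA)`.
#' @export
diagnose_brain_metastasis <- function(claims) {
  claims <- claims[claims$code == "C793", , drop = FALSE]
  if (!nrow(claims)) return(list(bm = FALSE, date = NA_real_))
  claims <- claims[order(claims$service_date), , drop = FALSE]
  inpat <- claims$service_date[claims$setting == "inpatient"]
  outpat <- claims$service_date[claims$setting == "outpatient"]
  d_in <- if (length(inpat)) inpat[1] else Inf
  d_out <- if (length(outpat) >= 2) outpat[2] else Inf
  d <- min(d_in, d_out)
  if (is.finite(d)) list(bm = TRUE, date = d) else list(bm = FALSE, date = NA_real_)
}

# vectorized diagnosis over the whole claims table -> data.frame(id, dx_date)
.diagnose_all <- function(claims, ids) {
  dx <- rep(NA_real_, length(ids))
  if (nrow(claims)) {
    sp <- split(claims, claims$id)
    for (pid in names(sp)) {
      r <- diagnose_brain_metastasis(sp[[pid]])
      if (r$bm) dx[match(pid, ids)] <- r$date
    }
  }
  data.frame(id = ids, dx_date = dx)
}

endpoint_names <- c("os", "ttnt", "death_from_pf", "death_from_pp",
                    "ttnt_from_pf", "bm_from_pf", "bm_from_pp",
                    "ttnt_in_bmit", "death_in_bmit", "death_in_bmst",
                    "death_from_pf_bmfree", "death_from_pp_bmfree")

# cause-specific time/event under right censoring: event time te (Inf if
# never), competing times (censor the endpoint), admin censor tc.
# The death-from-PF and death-from-PP endpoints are defined in the
# three-state sense (pre/post start of subsequent therapy, regardless of
# brain metastasis), so that one fitted curve per endpoint serves both
# state-transition structures, mirroring the published input table.
.cause_specific <- function(te, competing, tc) {
  obs <- do.call(pmin, c(list(te, tc), competing))
  list(time = obs, event = is.finite(te) & te == obs)
}

#' Derive the study's time-to-event endpoints from records and claims
#'
#' Reconstructs each patient's *observed* path from the next-treatment
#' date (entry to PP or BMST), the claims-derived brain-metastasis
#' diagnosis date (not the latent onset), the death date, and
#' administrative censoring at the cut-off, then derives the twelve
#' time-to-event datasets used by the three model structures: `os`,
#' `ttnt` (next treatment or death, the progression-free-survival
#' proxy), `death_from_pf`, `death_from_pp`, `ttnt_from_pf`,
#' `bm_from_pf`, `bm_from_pp`, `ttnt_in_bmit`, `death_in_bmit`,
#' `death_in_bmst`. State-conditional endpoints use the state-entry date
#' as clock origin and include only patients observed entering the
#' state. `death_from_pf` and `death_from_pp` are defined in the
#' three-state sense -- death before any subsequent therapy (from index,
#' all patients, censored at the therapy switch) and death after
#' starting subsequent therapy (from that start) -- so each is fitted
#' once and drives the death transitions of both state-transition
#' structures; the brain-metastasis death endpoints are their
#' within-BM-state refinements.
#'
#' @param records A `patient_cohort` (possibly a matched subset).
#' @param claims Output of [emit_claims()].
#' @param cutoff Administrative cut-off (days from accrual origin).
#' @return Named list of data frames (`id`, `time`, `event`, `arm`),
#'   one per endpoint; empty at-risk sets yield an empty data frame with
#'   a warning.
#' @export
derive_endpoint_datasets <- function(records, claims,
                                     cutoff = attr(records, "config")$study_cutoff) {
  stopifnot(inherits(records, "patient_cohort"))
  if (any(cutoff < records$index_date)) {
    stop("cutoff precedes some index dates", call. = FALSE)
  }
  tc <- cutoff - records$index_date
  dx <- .diagnose_all(claims, records$id)$dx_date
  td <- ifelse(is.na(records$t_death), Inf, records$t_death)
  t_nt <- pmin(ifelse(is.na(records$t_pp_entry), Inf, records$t_pp_entry),
               ifelse(is.na(records$t_bmst_entry), Inf, records$t_bmst_entry))
  t_dx <- ifelse(is.na(dx), Inf, dx)
  t_dx[t_dx > pmin(td, tc)] <- Inf   # diagnosis after death/censor is unobserved

  # observed-path state machine on {dx, nt, death}; BM precedes treatment
  # switch on ties
  start_bmit <- records$baseline_bm | t_dx == 0
  # observed entries (days from index); Inf = never observed
  o_pp <- ifelse(!start_bmit & t_nt < pmin(t_dx, td) & t_nt <= tc, t_nt, Inf)
  o_bmit <- ifelse(start_bmit, 0,
                   ifelse(t_dx <= pmin(t_nt, td) & t_dx <= tc, t_dx, Inf))
  # BMST: from PP at BM diagnosis, or from BMIT at next treatment
  o_bmst <- rep(Inf, nrow(records))
  from_pp <- is.finite(o_pp) & t_dx > o_pp & t_dx <= pmin(td, tc) & is.finite(t_dx)
  o_bmst[from_pp] <- t_dx[from_pp]
  from_bmit <- is.finite(o_bmit) & t_nt > o_bmit & t_nt <= pmin(td, tc) & is.finite(t_nt)
  o_bmst[from_bmit] <- t_nt[from_bmit]

  mk <- function(ix, time, event, name) {
    keep <- ix & time > 0
    d <- data.frame(id = records$id[keep], time = time[keep],
                    event = event[keep], arm = records$arm[keep])
    if (!nrow(d)) warning(sprintf("empty at-risk set for endpoint '%s'", name),
                          call. = FALSE)
    attr(d, "endpoint") <- name
    d
  }
  all_ix <- rep(TRUE, nrow(records))
  ep <- list()
  cs <- .cause_specific(td, list(), tc)
  ep$os <- mk(all_ix, cs$time, cs$event, "os")
  t_star <- pmin(t_nt, td)
  cs <- .cause_specific(t_star, list(), tc)
  ep$ttnt <- mk(all_ix, cs$time, cs$event, "ttnt")

  # observed start of subsequent therapy (three-state progression)
  t_nt_obs <- ifelse(t_nt <= pmin(td, tc), t_nt, Inf)

  # death before any subsequent therapy, all patients, from index
  cs <- .cause_specific(td, list(t_nt_obs), tc)
  ep$death_from_pf <- mk(all_ix, cs$time, cs$event, "death_from_pf")

  pf <- !start_bmit
  cs <- .cause_specific(o_pp, list(o_bmit, td), tc)
  ep$ttnt_from_pf <- mk(pf, cs$time, cs$event, "ttnt_from_pf")
  cs <- .cause_specific(o_bmit, list(o_pp, td), tc)
  ep$bm_from_pf <- mk(pf, cs$time, cs$event, "bm_from_pf")

  # death after starting subsequent therapy, from that start
  post_nt <- is.finite(t_nt_obs)
  cs <- .cause_specific(td - t_nt_obs, list(), tc - t_nt_obs)
  ep$death_from_pp <- mk(post_nt, cs$time, cs$event, "death_from_pp")

  in_pp <- is.finite(o_pp)
  cs <- .cause_specific(o_bmst - o_pp, list(td - o_pp), tc - o_pp)
  ep$bm_from_pp <- mk(in_pp, cs$time, cs$event, "bm_from_pp")

  # BM-free cause-specific refinements for the 5-state structure: death
  # from PF censored at any BM-state entry, death from (5-state) PP
  # censored at BMST entry
  cs <- .cause_specific(td, list(o_pp, o_bmit), tc)
  ep$death_from_pf_bmfree <- mk(pf, cs$time, cs$event, "death_from_pf_bmfree")
  cs <- .cause_specific(td - o_pp, list(o_bmst - o_pp), tc - o_pp)
  ep$death_from_pp_bmfree <- mk(in_pp, cs$time, cs$event, "death_from_pp_bmfree")

  in_bmit <- is.finite(o_bmit)
  cs <- .cause_specific(o_bmst - o_bmit, list(td - o_bmit), tc - o_bmit)
  ep$ttnt_in_bmit <- mk(in_bmit, cs$time, cs$event, "ttnt_in_bmit")
  cs <- .cause_specific(td - o_bmit, list(o_bmst - o_bmit), tc - o_bmit)
  ep$death_in_bmit <- mk(in_bmit, cs$time, cs$event, "death_in_bmit")

  in_bmst <- is.finite(o_bmst)
  cs <- .cause_specific(td - o_bmst, list(), tc - o_bmst)
  ep$death_in_bmst <- mk(in_bmst, cs$time, cs$event, "death_in_bmst")
  ep
}
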