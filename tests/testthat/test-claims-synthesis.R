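zero_death_hazards <- function() {
  hz <- default_hazards()
  for (arm in c("A", "B")) {
    for (e in c("pf_death", "pp_death", "bmit_death", "bmst_death")) {
      hz[[arm]][[e]] <- list(family = "exponential", params = c(rate = 0))
    }
  }
  hz
}

test_that("cohort generation is deterministic and respects arm sizes", {
  cfg <- sim_config(n_per_arm = 735L, seed = 11L)
  r1 <- generate_cohorts(cfg)
  r2 <- generate_cohorts(cfg)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 1470L)
  expect_equal(as.vector(table(r1$arm)), c(735L, 735L))
  # claims and endpoints inherit the determinism
  c1 <- emit_claims(r1); c2 <- emit_claims(r2)
  expect_identical(c1, c2)
  e1 <- derive_endpoint_datasets(r1, c1)
  e2 <- derive_endpoint_datasets(r2, c2)
  expect_identical(e1, e2)
})

test_that("zero death hazards produce no deaths", {
  cfg <- sim_config(n_per_arm = 100L, seed = 3L, hazards = zero_death_hazards())
  rec <- generate_cohorts(cfg)
  expect_true(all(is.na(rec$t_death)))
})

test_that("invalid hazard specs fail naming the edge", {
  hz <- default_hazards()
  hz$A$pp_death <- list(family = "weibull", params = c(shape = -2, scale = 100))
  expect_error(sim_config(hazards = hz), "A:pp_death")
  hz$A$pp_death <- list(family = "nosuch", params = c(rate = 1))
  expect_error(sim_config(hazards = hz), "nosuch")
})

test_that("exponential death times have the closed-form mean", {
  # all-cause death hazard 0.001/day from every state, no competing exits
  exp0 <- list(family = "exponential", params = c(rate = 0))
  exp1 <- list(family = "exponential", params = c(rate = 0.001))
  hz <- list()
  for (arm in c("A", "B")) {
    hz[[arm]] <- list(pf_pp = exp0, pf_death = exp1, pf_bm = exp0,
                      pp_death = exp1, pp_bm = exp0, bmit_ttnt = exp0,
                      bmit_death = exp1, bmst_death = exp1)
  }
  cfg <- sim_config(n_per_arm = 5000L, seed = 5L, baseline_bm_fraction = 0,
                    hazards = hz)
  rec <- generate_cohorts(cfg)  # 10,000 patients
  se <- 1000 / sqrt(nrow(rec))
  expect_lt(abs(mean(rec$t_death) - 1000), 3 * se)
})

test_that("realized paths follow the minimum competing latent time", {
  cfg <- sim_config(n_per_arm = 300L, seed = 9L)
  rec <- generate_cohorts(cfg)
  pf <- rec[!rec$baseline_bm, ]
  m <- pmin(pf$lat_pf_bm, pf$lat_pf_pp, pf$lat_pf_death)
  went_bm <- !is.na(pf$t_bmit_entry)
  went_pp <- !is.na(pf$t_pp_entry)
  died_pf <- !went_bm & !went_pp & !is.na(pf$t_death)
  expect_true(all(pf$t_bmit_entry[went_bm] == m[went_bm]))
  expect_true(all(pf$lat_pf_bm[went_bm] <= pmin(pf$lat_pf_pp, pf$lat_pf_death)[went_bm]))
  expect_true(all(pf$lat_pf_pp[went_pp] <= pmin(pf$lat_pf_bm, pf$lat_pf_death)[went_pp]))
  expect_true(all(pf$lat_pf_death[died_pf] <= pmin(pf$lat_pf_bm, pf$lat_pf_pp)[died_pf]))
  # PP exits
  pp <- rec[!is.na(rec$t_pp_entry), ]
  to_bmst <- !is.na(pp$t_bmst_entry)
  expect_true(all(pp$lat_pp_bm[to_bmst] <= pp$lat_pp_death[to_bmst]))
})

test_that("claims follow the diagnosis rule by construction", {
  cfg <- sim_config(n_per_arm = 400L, seed = 21L, claim_noise_fraction = 0)
  rec <- generate_cohorts(cfg)
  cl <- emit_claims(rec)
  cens <- censor_time(rec)
  bm_entry <- ifelse(!is.na(rec$t_bmit_entry), rec$t_bmit_entry,
                     ifelse(!is.na(rec$t_pp_entry), rec$t_bmst_entry, NA))
  observed_bm <- !is.na(bm_entry) &
    bm_entry <= pmin(cens, ifelse(is.na(rec$t_death), Inf, rec$t_death))
  # with zero noise, exactly the observed-BM patients carry claims
  expect_setequal(unique(cl$id), rec$id[observed_bm])
  # every claim carrier satisfies the rule at/after BM entry
  for (pid in unique(cl$id)) {
    pc <- cl[cl$id == pid, ]
    dx <- diagnose_brain_metastasis(pc)
    expect_true(dx$bm)
    expect_gte(dx$date, bm_entry[rec$id == pid])
  }
})

test_that("noise claims are single outpatient visits at the configured rate", {
  cfg <- sim_config(n_per_arm = 5000L, seed = 31L, claim_noise_fraction = 0.1,
                    baseline_bm_fraction = 0)
  rec <- generate_cohorts(cfg)
  cl <- emit_claims(rec)
  never_bm <- is.na(rec$t_bmit_entry) & is.na(rec$t_bmst_entry)
  noise_ids <- intersect(unique(cl$id), rec$id[never_bm])
  # single outpatient claim each: diagnosis rule not satisfied
  for (pid in noise_ids[seq_len(min(20, length(noise_ids)))]) {
    expect_false(diagnose_brain_metastasis(cl[cl$id == pid, ])$bm)
  }
  n_never <- sum(never_bm)
  expect_lt(abs(length(noise_ids) - 0.1 * n_never),
            3 * sqrt(n_never * 0.1 * 0.9))
})

test_that("diagnosis rule handles the inpatient/outpatient patterns", {
  one_out <- data.frame(service_date = 10, setting = "outpatient", code = "C793")
  expect_false(diagnose_brain_metastasis(one_out)$bm)
  one_in <- data.frame(service_date = 30, setting = "inpatient", code = "C793")
  expect_equal(diagnose_brain_metastasis(one_in), list(bm = TRUE, date = 30))
  mixed <- data.frame(service_date = c(10, 40, 50),
                      setting = c("outpatient", "outpatient", "inpatient"),
                      code = "C793")
  # second outpatient claim (day 40) beats the inpatient claim (day 50)
  expect_equal(diagnose_brain_metastasis(mixed), list(bm = TRUE, date = 40))
  other_code <- data.frame(service_date = 5, setting = "inpatient", code = "C780")
  expect_false(diagnose_brain_metastasis(other_code)$bm)
})

test_that("hand-written patient paths yield the hand-computed endpoint table", {
  cfg <- sim_config(n_per_arm = 2L, seed = 1L)
  rec <- generate_cohorts(cfg)
  # overwrite with three crafted paths + one filler, cutoff at day 1825
  # P1 (A): index 0, PF -> PP@100 -> death@300
  # P2 (A): index 25, PF -> BMIT@200(dx) -> BMST@400 -> alive at cutoff
  # P3 (B): index 0, baseline BM (BMIT@0) -> death@150
  # P4 (B): index 0, PF forever (alive, no events)
  rec$index_date <- c(0, 25, 0, 0)
  rec$baseline_bm <- c(FALSE, FALSE, TRUE, FALSE)
  rec$t_pp_entry <- c(100, NA, NA, NA)
  rec$t_bmit_entry <- c(NA, 200, 0, NA)
  rec$t_bmst_entry <- c(NA, 400, NA, NA)
  rec$t_death <- c(300, NA, 150, NA)
  claims <- data.frame(
    id = c(rec$id[2], rec$id[3]),
    service_date = c(200, 0), setting = "inpatient", code = "C793")
  ep <- suppressWarnings(derive_endpoint_datasets(rec, claims, cutoff = 1825))
  expect_equal(ep$os$time, c(300, 1800, 150, 1825))
  expect_equal(ep$os$event, c(TRUE, FALSE, TRUE, FALSE))
  # ttnt: P1 event@100 (next treatment), P2 event@400 (BMST entry),
  # P3 dies@150 with no next treatment -> event, P4 censored
  expect_equal(ep$ttnt$time, c(100, 400, 150, 1825))
  expect_equal(ep$ttnt$event, c(TRUE, TRUE, TRUE, FALSE))
  # death before subsequent therapy: all four at risk from index;
  # P3 dies in BMIT without a therapy switch -> pre-switch death event
  expect_equal(ep$death_from_pf$time, c(100, 400, 150, 1825))
  expect_equal(ep$death_from_pf$event, c(FALSE, FALSE, TRUE, FALSE))
  # PF starters: P1, P2, P4
  expect_equal(ep$ttnt_from_pf$time, c(100, 200, 1825))
  expect_equal(ep$ttnt_from_pf$event, c(TRUE, FALSE, FALSE))
  expect_equal(ep$bm_from_pf$time, c(100, 200, 1825))
  expect_equal(ep$bm_from_pf$event, c(FALSE, TRUE, FALSE))
  # death after subsequent therapy: P1 (switch@100, dies 200 later),
  # P2 (switch@400, censored 1400 later)
  expect_equal(ep$death_from_pp$time, c(200, 1400))
  expect_equal(ep$death_from_pp$event, c(TRUE, FALSE))
  # 5-state PP entrants: P1 only
  expect_equal(ep$bm_from_pp$time, 200)
  expect_false(ep$bm_from_pp$event[1])
  # BM-free refinements: P1 censored at switch, P2 at BM diagnosis
  expect_equal(ep$death_from_pf_bmfree$time, c(100, 200, 1825))
  expect_equal(ep$death_from_pf_bmfree$event, c(FALSE, FALSE, FALSE))
  expect_equal(ep$death_from_pp_bmfree$time, 200)
  expect_true(ep$death_from_pp_bmfree$event[1])
  # BMIT entrants: P2 (entry 200), P3 (entry 0)
  expect_equal(ep$ttnt_in_bmit$time, c(200, 150))
  expect_equal(ep$ttnt_in_bmit$event, c(TRUE, FALSE))
  expect_equal(ep$death_in_bmit$time, c(200, 150))
  expect_equal(ep$death_in_bmit$event, c(FALSE, TRUE))
  # BMST entrants: P2 only, censored 1400 days after entry (index 25)
  expect_equal(ep$death_in_bmst$time, 1400)
  expect_false(ep$death_in_bmst$event[1])
})

test_that("raising the cutoff never decreases observed event counts", {
  cfg <- sim_config(n_per_arm = 300L, seed = 17L)
  rec <- generate_cohorts(cfg)
  cl <- emit_claims(rec)
  counts <- vapply(c(1200, 1500, 1825), function(ct) {
    ep <- suppressWarnings(derive_endpoint_datasets(rec, cl, cutoff = ct))
    vapply(ep, function(d) sum(d$event), 0)
  }, numeric(12))
  expect_true(all(diff(t(counts)) >= 0))
})

test_that("deaths partition by therapy phase and BM refinements nest", {
  cfg <- sim_config(n_per_arm = 400L, seed = 23L)
  rec <- generate_cohorts(cfg)
  cl <- emit_claims(rec)
  ep <- derive_endpoint_datasets(rec, cl)
  os_deaths <- ep$os$id[ep$os$event]
  pre <- ep$death_from_pf$id[ep$death_from_pf$event]
  post <- ep$death_from_pp$id[ep$death_from_pp$event]
  # every observed death is either before or after the therapy switch
  expect_length(intersect(pre, post), 0)
  expect_setequal(c(pre, post), os_deaths)
  # deaths inside the BM states refine the two phases
  expect_true(all(ep$death_in_bmit$id[ep$death_in_bmit$event] %in% pre))
  expect_true(all(ep$death_in_bmst$id[ep$death_in_bmst$event] %in% post))
})

test_that("synthetic OS Kaplan-Meier converges to the true survival", {
  # single absorbing transition: all-cause death exponential 0.0015/day
  exp0 <- list(family = "exponential", params = c(rate = 0))
  exp1 <- list(family = "exponential", params = c(rate = 0.0015))
  hz <- list()
  for (arm in c("A", "B")) {
    hz[[arm]] <- list(pf_pp = exp0, pf_death = exp1, pf_bm = exp0,
                      pp_death = exp1, pp_bm = exp0, bmit_ttnt = exp0,
                      bmit_death = exp1, bmst_death = exp1)
  }
  cfg <- sim_config(n_per_arm = 10000L, seed = 41L, baseline_bm_fraction = 0,
                    study_cutoff = 3000, index_dispersion = 0, hazards = hz)
  rec <- generate_cohorts(cfg)
  ep <- suppressWarnings(derive_endpoint_datasets(rec, emit_claims(rec)))
  km <- km_estimate(ep$os)
  at <- seq(100, 2000, by = 100)
  idx <- findInterval(at, km$time)
  s_hat <- c(1, km$surv)[idx + 1]
  se <- c(0, km$greenwood_se)[idx + 1]
  expect_true(all(abs(s_hat - exp(-0.0015 * at)) <= 4 * pmax(se, 1e-4)))
})

test_that("greedy matching reproduces hand-enumerated pairs", {
  rec <- data.frame(id = c("A1", "A2", "B1", "B2"),
                    arm = c("A", "A", "B", "B"),
                    score = c(0.9, 0.2, 0.85, 0.25))
  # logit-monotone covariate: matching on `score` directly
  m <- propensity_match(rec, covariates = "score")
  pairs <- m$pairs[order(m$pairs$id_a), ]
  expect_equal(pairs$id_a, c("A1", "A2"))
  expect_equal(pairs$id_b, c("B1", "B2"))
})

test_that("matching a balanced cohort yields SMD below 0.1", {
  cfg <- sim_config(n_per_arm = 735L, seed = 13L)
  rec <- generate_cohorts(cfg)
  m <- propensity_match(rec)
  expect_true(all(abs(m$smd_after) < 0.1))
  expect_true(all(abs(m$smd_after) <= abs(m$smd_before) + 1e-9))
  expect_equal(nrow(m$pairs), 735L)
  expect_false(any(duplicated(c(m$pairs$id_a, m$pairs$id_b))))
})

test_that("matching reduces a deliberate age imbalance", {
  cfg <- sim_config(n_per_arm = 500L, seed = 19L, age_shift_b = 4)
  rec <- generate_cohorts(cfg)
  m <- propensity_match(rec, caliper = 0.2)
  expect_lt(abs(m$smd_after[["age"]]), abs(m$smd_before[["age"]]))
})

test_that("degenerate covariates report SMD 0 with a warning", {
  rec <- data.frame(id = c("A1", "A2", "B1", "B2"),
                    arm = c("A", "A", "B", "B"),
                    flat = c(1, 1, 1, 1))
  expect_warning(s <- standardized_mean_difference(rec, "flat"), "zero variance")
  expect_equal(unname(s), 0)
})
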