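# shared fixture builders

exp_model <- function(rate) survmodel("exponential", c(rate = rate))
wei_model <- function(shape, scale) survmodel("weibull",
                                              c(shape = shape, scale = scale))

# simulated right-censored sample from a survmodel family with
# administrative censoring at `cens` (Inf = none)
sim_surv_data <- function(n, family, params, cens = Inf) {
  t <- oncostm:::rsurv(n, list(family = family, params = params))
  data.frame(time = pmin(t, cens), event = t <= cens)
}

# a tiny three-state exponential model set for the 3-state engine:
# ttnt is the exact product of the progression and death curves
exp_stm3_models <- function(l_prog, l_death_pf, l_death_pp) {
  list(ttnt = exp_model(l_prog + l_death_pf),
       death_from_pf = exp_model(l_death_pf),
       death_from_pp = exp_model(l_death_pp))
}

exp_stm5_models <- function(l_prog, l_death_pf, l_bm, l_death_pp, l_bm_pp,
                            l_bmit_nt, l_bmit_death, l_bmst_death) {
  list(ttnt_from_pf = exp_model(l_prog), death_from_pf = exp_model(l_death_pf),
       bm_from_pf = exp_model(l_bm), death_from_pp = exp_model(l_death_pp),
       bm_from_pp = exp_model(l_bm_pp), ttnt_in_bmit = exp_model(l_bmit_nt),
       death_in_bmit = exp_model(l_bmit_death),
       death_in_bmst = exp_model(l_bmst_death))
}

# independent time-homogeneous oracle: per-cycle transition matrix built
# directly from exponential rates with the hazard-split allocation, then
# powered up. `rates` is a list state -> named vector of exit rates.
matrix_power_trace <- function(states, rates, init, n_cycles, cycle) {
  P <- diag(length(states))
  dimnames(P) <- list(states, states)
  for (s in names(rates)) {
    lam <- rates[[s]]
    tot <- sum(lam)
    Q <- 1 - exp(-cycle * tot)
    P[s, s] <- 1 - Q
    for (tgt in names(lam)) P[s, tgt] <- Q * lam[[tgt]] / tot
  }
  occ <- matrix(0, n_cycles + 1L, length(states),
                dimnames = list(NULL, states))
  v <- init
  for (k in 0:n_cycles) {
    occ[k + 1L, ] <- v
    v <- as.numeric(v %*% P)
  }
  occ
}

# the full default study is expensive; memoize it for tests that share it
.study_cache <- new.env(parent = emptyenv())
cached_default_study <- function(seed = 20260925) {
  key <- paste0("s", seed)
  if (is.null(.study_cache[[key]])) {
    .study_cache[[key]] <- run_study(default_study_config(seed = seed),
                                     sensitivity = FALSE)
  }
  .study_cache[[key]]
}
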