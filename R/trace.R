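#' Conditional probability of leaving a state within one cycle
#'
#' For a driving survival curve `S` and clock time `t` at the cycle
#' start, the probability of the event occurring during a cycle of
#' length `c` is `1 - S(t + c)/S(t)`, clipped to `[0, 1]`. When
#' `S(t) = 0` the whole remaining cohort exits (probability 1).
#'
#' @param model A `survmodel`.
#' @param t Clock time(s) at the cycle start (days; model time or
#'   time-in-state, depending on the transition).
#' @param cycle Cycle length in days (> 0).
#' @return Probability vector, same length as `t`.
#' @export
conditional_exit_probability <- function(model, t, cycle) {
  stopifnot(cycle > 0, all(t >= 0))
  s0 <- survival_at(model, t)
  s1 <- survival_at(model, t + cycle)
  q <- ifelse(s0 <= 0, 1, 1 - s1 / s0)
  pmin(pmax(q, 0), 1)
}

# Combine cause-specific conditional exit probabilities q (matrix layers x
# causes) into per-cause transition probabilities.
#   hazard_split: cause-specific cycle hazards lambda_i = -log(1-q_i)/c,
#     total exit Q = 1 - exp(-c * sum lambda), allocated proportionally to
#     lambda_i. Guarantees sum p <= 1 for any curves; reduces to q_i for a
#     single cause. q_i = 1 sends the whole exit to that cause.
#   subtraction: p_i = q_i, rescaled to sum 1 if they exceed it (capped).
# Returns list(p = matrix, capped = count of capped rows).
.combine_competing <- function(q, cycle, mode) {
  q <- pmin(pmax(q, 0), 1)
  if (ncol(q) == 1L) return(list(p = q, capped = 0L))
  if (mode == "subtraction") {
    tot <- rowSums(q)
    over <- tot > 1
    p <- q
    if (any(over)) p[over, ] <- q[over, , drop = FALSE] / tot[over]
    return(list(p = p, capped = sum(over)))
  }
  one <- q >= 1
  lam <- -log1p(-pmin(q, 1 - 1e-15)) / cycle
  lam_tot <- rowSums(lam)
  Q <- -expm1(-cycle * lam_tot)
  share <- lam / ifelse(lam_tot > 0, lam_tot, 1)
  p <- Q * share
  p[lam_tot == 0, ] <- 0
  any_one <- rowSums(one) > 0
  if (any(any_one)) {
    p[any_one, ] <- one[any_one, , drop = FALSE] / rowSums(one)[any_one]
  }
  list(p = p, capped = 0L)
}

#' Declare the 3-state structure (PF, PP, Death)
#'
#' Progression-free patients exit by death (driven by the
#' time-to-death-from-PF curve on the model-time clock) or progression;
#' the progression probability is derived from the TTNT curve, which
#' captures *total* PF exit (next treatment or death): the
#' progression-specific conditional probability is backed out as
#' `1 - (1 - q_ttnt)/(1 - q_death)`, floored at 0 when the two fitted
#' curves are inconsistent (`q_ttnt < q_death`), and the two causes are
#' then combined by the competing rule. Total PF exit equals `q_ttnt`
#' exactly under the default rule. Post-progression is a tunnel state:
#' occupancy is stratified by time since entry and dies by the
#' time-to-death-from-PP curve on the time-in-state clock.
#'
#' @param models Named list with `ttnt`, `death_from_pf`,
#'   `death_from_pp` (`survmodel`s).
#' @return A `model_structure` descriptor.
#' @export
stm3_structure <- function(models) {
  stopifnot(all(c("ttnt", "death_from_pf", "death_from_pp") %in% names(models)))
  structure(list(
    name = "STM3",
    states = c("PF", "PP", "Death"),
    init = c(PF = 1, PP = 0, Death = 0),
    exits = list(
      PF = list(kind = "total_minus_death", clock = "model",
                total = models$ttnt, death = models$death_from_pf,
                targets = c("PP", "Death")),
      PP = list(kind = "competing", clock = "state",
                curves = list(Death = models$death_from_pp))
    )
  ), class = "model_structure")
}

#' Declare the 5-state structure (PF, PP, BMIT, BMST, Death)
#'
#' Adds the two brain-metastasis states. PF has three competing exits on
#' the model-time clock: progression (TTNT-from-PF curve), death
#' (death-from-PF) and brain metastasis with continuing initial therapy
#' (time-to-brain-metastasis-from-PF). PP, BMIT and BMST are tunnel
#' states on the time-in-state clock: PP exits to death or (on brain
#' metastasis) to BMST; BMIT exits to BMST (next treatment) or death;
#' BMST exits to death. A fraction `initial_bm_fraction` of the cohort
#' (patients with brain-metastasis history at index) starts in BMIT.
#'
#' @param models Named list with `ttnt_from_pf`, `death_from_pf`,
#'   `bm_from_pf`, `death_from_pp`, `bm_from_pp`, `ttnt_in_bmit`,
#'   `death_in_bmit`, `death_in_bmst`.
#' @param initial_bm_fraction Probability of starting in BMIT.
#' @return A `model_structure` descriptor.
#' @export
stm5_structure <- function(models, initial_bm_fraction = 0) {
  need <- c("ttnt_from_pf", "death_from_pf", "bm_from_pf", "death_from_pp",
            "bm_from_pp", "ttnt_in_bmit", "death_in_bmit", "death_in_bmst")
  stopifnot(all(need %in% names(models)),
            initial_bm_fraction >= 0, initial_bm_fraction <= 1)
  f <- initial_bm_fraction
  structure(list(
    name = "STM5",
    states = c("PF", "PP", "BMIT", "BMST", "Death"),
    init = c(PF = 1 - f, PP = 0, BMIT = f, BMST = 0, Death = 0),
    exits = list(
      PF = list(kind = "competing", clock = "model",
                curves = list(PP = models$ttnt_from_pf,
                              Death = models$death_from_pf,
                              BMIT = models$bm_from_pf)),
      PP = list(kind = "competing", clock = "state",
                curves = list(Death = models$death_from_pp,
                              BMST = models$bm_from_pp)),
      BMIT = list(kind = "competing", clock = "state",
                  curves = list(BMST = models$ttnt_in_bmit,
                                Death = models$death_in_bmit)),
      BMST = list(kind = "competing", clock = "state",
                  curves = list(Death = models$death_in_bmst))
    )
  ), class = "model_structure")
}

# per-state transition probabilities for mass at clock times tvec.
# Returns list(p = matrix length(tvec) x targets (named), floors, capped).
.state_probs <- function(exit, tvec, cycle, mode) {
  if (exit$kind == "competing") {
    q <- vapply(exit$curves,
                function(m) conditional_exit_probability(m, tvec, cycle),
                numeric(length(tvec)))
    q <- matrix(q, nrow = length(tvec),
                dimnames = list(NULL, names(exit$curves)))
    cc <- .combine_competing(q, cycle, mode)
    list(p = cc$p, floors = 0L, capped = cc$capped)
  } else { # total_minus_death (3-state PF)
    q_tot <- conditional_exit_probability(exit$total, tvec, cycle)
    q_d <- conditional_exit_probability(exit$death, tvec, cycle)
    if (mode == "subtraction") {
      q_p <- q_tot - q_d
      floors <- sum(q_p < 0)
      q_p <- pmax(q_p, 0)
      p <- cbind(PP = q_p, Death = q_d)
      cap <- rowSums(p) > 1
      if (any(cap)) p[cap, ] <- p[cap, , drop = FALSE] / rowSums(p)[cap]
      list(p = p, floors = floors, capped = sum(cap))
    } else {
      # back out the progression-specific conditional probability so that
      # the competing combination reproduces total exit q_tot exactly
      q_p <- ifelse(q_d >= 1, 0, 1 - (1 - q_tot) / (1 - q_d))
      floors <- sum(q_p < 0)
      q_p <- pmin(pmax(q_p, 0), 1)
      cc <- .combine_competing(cbind(PP = q_p, Death = q_d), cycle, mode)
      list(p = cc$p, floors = floors, capped = cc$capped)
    }
  }
}

#' Build a cohort trace for a semi-Markov state-transition structure
#'
#' Cycle-by-cycle cohort simulation with time-dependent transition
#' probabilities. States whose exits run on the time-in-state clock are
#' expanded into tunnel layers, one per cycle since entry, up to the
#' full horizon (no truncation); entrants from other states start at
#' layer 0 at the next cycle boundary. Occupancy is recorded at cycle
#' boundaries `t = 0, c, 2c, ...`.
#'
#' @param structure A `model_structure` from [stm3_structure()] or
#'   [stm5_structure()].
#' @param horizon_days Time horizon (days); the number of cycles is
#'   `ceiling(horizon_days / cycle_days)`.
#' @param cycle_days Cycle length in days (default 21).
#' @param competing `"hazard_split"` (default) or `"subtraction"`, the
#'   rule combining competing conditional exit probabilities.
#' @return A `cohort_trace`: `time` (days at boundaries), `occupancy`
#'   (matrix, rows = boundaries, columns = states; rows sum to 1),
#'   `tunnels` (per tunnel state, matrix of occupancy by time-in-state
#'   layer), `events` (counts of floor/cap corrections).
#' @export
build_cohort_trace <- function(structure, horizon_days = 7 * 365.25,
                               cycle_days = 21,
                               competing = c("hazard_split", "subtraction")) {
  competing <- match.arg(competing)
  stopifnot(inherits(structure, "model_structure"), horizon_days > 0,
            cycle_days > 0)
  n_cycles <- ceiling(horizon_days / cycle_days)
  states <- structure$states
  transient <- names(structure$exits)
  n_l <- n_cycles + 1L
  # layer vectors: v[[s]][u+1] = mass with u completed cycles in state s
  v <- lapply(transient, function(s) {
    x <- numeric(n_l); x[1] <- structure$init[[s]]; x
  })
  names(v) <- transient
  death <- structure$init[["Death"]]
  occ <- matrix(0, n_l, length(states), dimnames = list(NULL, states))
  occ[1, transient] <- vapply(v, sum, 0)
  occ[1, "Death"] <- death
  tun <- lapply(v, function(x) { m <- matrix(0, n_l, n_l); m[1, ] <- x; m })
  floors <- 0L; capped <- 0L
  for (k in seq_len(n_cycles)) {
    inflow <- stats::setNames(numeric(length(states)), states)
    new_v <- lapply(v, function(x) numeric(n_l))
    for (s in transient) {
      mass <- v[[s]]
      live <- which(mass > 0)
      if (!length(live)) next
      exit <- structure$exits[[s]]
      tvec <- if (exit$clock == "model") rep((k - 1) * cycle_days, length(live))
              else (live - 1) * cycle_days
      sp <- .state_probs(exit, tvec, cycle_days, competing)
      floors <- floors + sp$floors; capped <- capped + sp$capped
      p <- sp$p
      for (j in colnames(p)) {
        inflow[[j]] <- inflow[[j]] + sum(mass[live] * p[, j])
      }
      stay <- mass[live] * pmax(1 - rowSums(p), 0)
      dest_layer <- pmin(live + 1L, n_l)
      for (ii in seq_along(live)) {
        new_v[[s]][dest_layer[ii]] <- new_v[[s]][dest_layer[ii]] + stay[ii]
      }
    }
    death <- death + inflow[["Death"]]
    for (s in transient) {
      if (inflow[[s]] > 0) new_v[[s]][1] <- new_v[[s]][1] + inflow[[s]]
    }
    v <- new_v
    occ[k + 1L, transient] <- vapply(v, sum, 0)
    occ[k + 1L, "Death"] <- death
    for (s in transient) tun[[s]][k + 1L, ] <- v[[s]]
  }
  structure(list(structure = structure$name, time = (0:n_cycles) * cycle_days,
                 cycle_days = cycle_days, states = states, occupancy = occ,
                 tunnels = tun,
                 events = c(tp1_floor = floors, prob_cap = capped)),
            class = "cohort_trace")
}

#' @rdname build_cohort_trace
#' @param models Named list of driving `survmodel`s, see
#'   [stm3_structure()].
#' @export
build_stm3_trace <- function(models, horizon_days = 7 * 365.25,
                             cycle_days = 21,
                             competing = c("hazard_split", "subtraction")) {
  tr <- build_cohort_trace(stm3_structure(models), horizon_days, cycle_days,
                           match.arg(competing))
  n_cycles <- length(tr$time) - 1L
  if (tr$events[["tp1_floor"]] > 0.1 * n_cycles) {
    warning(sprintf(
      "TTNT and death-from-PF curves inconsistent: progression floor hit in %d of %d cycles",
      tr$events[["tp1_floor"]], n_cycles), call. = FALSE)
  }
  tr
}

#' @rdname build_cohort_trace
#' @param initial_bm_fraction Fraction of the cohort starting in BMIT.
#' @export
build_stm5_trace <- function(models, initial_bm_fraction = 0,
                             horizon_days = 7 * 365.25, cycle_days = 21,
                             competing = c("hazard_split", "subtraction")) {
  tr <- build_cohort_trace(stm5_structure(models, initial_bm_fraction),
                           horizon_days, cycle_days, match.arg(competing))
  if (tr$events[["prob_cap"]] > 0) {
    warning(sprintf("competing-exit cap triggered %d times",
                    tr$events[["prob_cap"]]), call. = FALSE)
  }
  tr
}

#' Build a partitioned-survival trace
#'
#' State occupancy is read directly off the extrapolated curves at each
#' cycle boundary: dead = `1 - S_OS(t)`, progression-free =
#' `min(S_TTNT(t), S_OS(t))` (the cap keeps post-progression occupancy
#' non-negative where the fitted curves cross), post-progression =
#' `S_OS(t) - PF`.
#'
#' @param os_model,ttnt_model `survmodel`s for overall survival and time
#'   to next treatment.
#' @inheritParams build_cohort_trace
#' @return A `cohort_trace` with states PF, PP, Death; `events` counts
#'   cycles where the crossing cap was active.
#' @export
build_psm_trace <- function(os_model, ttnt_model, horizon_days = 7 * 365.25,
                            cycle_days = 21) {
  stopifnot(horizon_days > 0, cycle_days > 0)
  n_cycles <- ceiling(horizon_days / cycle_days)
  tt <- (0:n_cycles) * cycle_days
  s_os <- survival_at(os_model, tt)
  s_tt <- survival_at(ttnt_model, tt)
  pf <- pmin(s_tt, s_os)
  occ <- cbind(PF = pf, PP = s_os - pf, Death = 1 - s_os)
  structure(list(structure = "PSM", time = tt, cycle_days = cycle_days,
                 states = colnames(occ), occupancy = occ, tunnels = NULL,
                 events = c(crossing_cap = sum(s_tt > s_os))),
            class = "cohort_trace")
}

#' Individual-level microsimulation of a state-transition structure
#'
#' Simulates `n` individuals cycle by cycle using exactly the same
#' per-cycle transition probabilities and clocks as the cohort engine,
#' and returns the empirical occupancy trace. Used as a stochastic
#' oracle for validating the cohort traces.
#'
#' @inheritParams build_cohort_trace
#' @param n Number of individuals.
#' @param seed Integer seed.
#' @return A `cohort_trace` with empirical occupancy proportions.
#' @export
microsimulate <- function(structure, n, seed, horizon_days = 7 * 365.25,
                          cycle_days = 21,
                          competing = c("hazard_split", "subtraction")) {
  competing <- match.arg(competing)
  stopifnot(n >= 1)
  set.seed(seed)
  n_cycles <- ceiling(horizon_days / cycle_days)
  states <- structure$states
  n_states <- length(states)
  state_id <- stats::setNames(seq_len(n_states), states)
  st <- state_id[sample(states, n, replace = TRUE, prob = structure$init)]
  u <- integer(n)
  occ <- matrix(0, n_cycles + 1L, n_states, dimnames = list(NULL, states))
  occ[1, ] <- tabulate(st, n_states) / n
  death_id <- state_id[["Death"]]
  for (k in seq_len(n_cycles)) {
    new_st <- st; new_u <- u
    for (s in names(structure$exits)) {
      sid <- state_id[[s]]
      idx <- which(st == sid)
      if (!length(idx)) next
      exit <- structure$exits[[s]]
      if (exit$clock == "model") {
        groups <- list(idx)
        tvals <- (k - 1) * cycle_days
      } else {
        uu <- u[idx]
        uniq <- sort(unique(uu))
        groups <- lapply(uniq, function(x) idx[uu == x])
        tvals <- uniq * cycle_days
      }
      for (g in seq_along(groups)) {
        gi <- groups[[g]]
        sp <- .state_probs(exit, tvals[g], cycle_days, competing)
        p <- sp$p[1, ]
        cum <- cumsum(c(p, 1 - sum(p)))
        r <- stats::runif(length(gi))
        dest <- findInterval(r, cum, left.open = TRUE) + 1L
        targets <- c(names(p), s)
        for (jj in seq_along(targets)) {
          sel <- gi[dest == jj]
          if (!length(sel)) next
          if (targets[jj] == s) {
            new_u[sel] <- u[sel] + 1L
          } else {
            new_st[sel] <- state_id[[targets[jj]]]
            new_u[sel] <- 0L
          }
        }
      }
    }
    st <- new_st; u <- new_u
    occ[k + 1L, ] <- tabulate(st, n_states) / n
  }
  structure(list(structure = paste0(structure$name, "-micro"),
                 time = (0:n_cycles) * cycle_days, cycle_days = cycle_days,
                 states = states, occupancy = occ, tunnels = NULL,
                 events = c()),
            class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat(sprintf("<cohort_trace: %s, %d cycles of %g days>\n",
              x$structure, length(x$time) - 1L, x$cycle_days))
  print(utils::head(round(x$occupancy, 4)))
  invisible(x)
}
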