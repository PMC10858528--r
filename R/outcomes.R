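#' Trapezoidal area under a curve
#'
#' @param time Strictly increasing grid.
#' @param values Curve values at the grid points (same length).
#' @return `sum((t[i+1]-t[i]) * (v[i]+v[i+1]) / 2)`.
#' @export
auc_trapezoid <- function(time, values) {
  if (length(time) != length(values)) stop("length mismatch", call. = FALSE)
  if (any(diff(time) <= 0)) stop("time grid must be strictly increasing", call. = FALSE)
  sum(diff(time) * (utils::head(values, -1) + utils::tail(values, -1)) / 2)
}

#' Discounting specification
#'
#' @param annual_rate Annual discount rate (default 0.045, the South
#'   Korean HTA requirement). Must exceed -1.
#' @return A `discount_spec` list.
#' @export
discount_spec <- function(annual_rate = 0.045) {
  stopifnot(annual_rate > -1)
  structure(list(annual_rate = annual_rate), class = "discount_spec")
}

#' Health-state utility set
#'
#' Per-arm utilities for the progression-free and post-progression
#' states, shared utilities for the two brain-metastasis states.
#' Post-progression and BMST utilities are derived from the PF and BMIT
#' values by a fixed progression decrement.
#'
#' @param pf Named vector `c(A = , B = )` of progression-free utilities
#'   (defaults 0.800 and 0.730).
#' @param bmit Utility of brain metastasis with continuing initial
#'   therapy (default 0.520, shared between arms).
#' @param decrement Utility decrease on progression (default 0.042),
#'   applied to PF (giving PP) and to BMIT (giving BMST).
#' @return A `utility_set` list with elements `PF`, `PP` (per-arm) and
#'   `BMIT`, `BMST` (scalars).
#' @export
utility_set <- function(pf = c(A = 0.800, B = 0.730), bmit = 0.520,
                        decrement = 0.042) {
  u <- list(PF = pf, PP = pf - decrement, BMIT = bmit, BMST = bmit - decrement,
            decrement = decrement)
  vals <- unlist(u[c("PF", "PP", "BMIT", "BMST")])
  if (any(vals < 0 | vals > 1)) stop("utilities must lie in [0, 1]", call. = FALSE)
  structure(u, class = "utility_set")
}

# utility applicable to state `state` for arm `arm`
.state_utility <- function(utilities, state, arm) {
  switch(state,
         PF = utilities$PF[[arm]], PP = utilities$PP[[arm]],
         BMIT = utilities$BMIT, BMST = utilities$BMST,
         Death = 0,
         stop(sprintf("unknown state '%s'", state), call. = FALSE))
}

#' Discounted value of time spent in one state
#'
#' Trapezoidal integration of `occupancy(t) * weight * (1 +
#' rate)^(-t/365.25)` over the trace grid, returned in years. With
#' `weight = 1` this is (discounted) life-years in the state; with the
#' state utility it is the QALY contribution. Discounting is continuous
#' in time inside the trapezoid weights.
#'
#' @param trace A `cohort_trace`.
#' @param state State name (must be present in the trace).
#' @param weight Utility weight (1 for LY).
#' @param discount A [discount_spec()].
#' @return Value in (quality-adjusted) years.
#' @export
discounted_state_value <- function(trace, state, weight = 1,
                                   discount = discount_spec()) {
  if (!state %in% trace$states) stop(sprintf("state '%s' not in trace", state),
                                     call. = FALSE)
  occ <- trace$occupancy[, state]
  disc <- (1 + discount$annual_rate)^(-trace$time / 365.25)
  auc_trapezoid(trace$time, occ * disc * weight) / 365.25
}

#' Summarize LY and QALY outcomes for a pair of traces
#'
#' Computes discounted and undiscounted life-years and QALYs, total and
#' by health state, for each arm, and the incremental values (arm A
#' minus arm B). The death state contributes zero to both.
#'
#' @param trace_a,trace_b `cohort_trace`s for arms A and B; must share
#'   grid and state set.
#' @param utilities A [utility_set()].
#' @param discount A [discount_spec()].
#' @return An `outcome_summary`: `by_state` (long data frame with arm,
#'   state, metric, discounted flag, value), `totals`, `incremental`
#'   (per state and total), and the inputs used.
#' @export
summarize_outcomes <- function(trace_a, trace_b, utilities = utility_set(),
                               discount = discount_spec()) {
  if (!identical(trace_a$states, trace_b$states) ||
      !isTRUE(all.equal(trace_a$time, trace_b$time))) {
    stop("traces must share grid and structure", call. = FALSE)
  }
  states <- setdiff(trace_a$states, "Death")
  no_disc <- discount_spec(0)
  rows <- list()
  for (arm in c("A", "B")) {
    tr <- if (arm == "A") trace_a else trace_b
    for (s in states) {
      u <- .state_utility(utilities, s, arm)
      rows[[length(rows) + 1L]] <- data.frame(
        arm = arm, state = s,
        ly = discounted_state_value(tr, s, 1, discount),
        qaly = discounted_state_value(tr, s, u, discount),
        ly_undisc = discounted_state_value(tr, s, 1, no_disc),
        qaly_undisc = discounted_state_value(tr, s, u, no_disc))
    }
  }
  by_state <- do.call(rbind, rows)
  totals <- stats::aggregate(by_state[c("ly", "qaly", "ly_undisc", "qaly_undisc")],
                             by = list(arm = by_state$arm), FUN = sum)
  inc_state <- by_state[by_state$arm == "A", -1]
  b_side <- by_state[by_state$arm == "B", -1]
  stopifnot(identical(inc_state$state, b_side$state))
  for (v in c("ly", "qaly", "ly_undisc", "qaly_undisc")) {
    inc_state[[v]] <- inc_state[[v]] - b_side[[v]]
  }
  inc_total <- totals[totals$arm == "A", -1] - totals[totals$arm == "B", -1]
  structure(list(by_state = by_state, totals = totals,
                 incremental = list(by_state = inc_state, total = inc_total),
                 utilities = utilities, discount = discount,
                 structure = trace_a$structure),
            class = "outcome_summary")
}

#' @export
print.outcome_summary <- function(x, ...) {
  cat(sprintf("<outcome_summary: %s>\n", x$structure))
  cat("incremental (A - B), discounted:\n")
  print(round(x$incremental$total[c("ly", "qaly")], 3))
  invisible(x)
}

# round half away from zero to `digits`
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Compare incremental outcomes across model structures
#'
#' Pairwise relative differences of incremental LY and QALY between
#' structures, reported as integer percentages `100 * (x - ref)/ref`
#' rounded half away from zero. A zero reference yields `NA` rather
#' than an infinite percentage.
#'
#' @param summaries Named list of `outcome_summary` objects (>= 2).
#' @return Data frame: structure, reference, metric, value, ref_value,
#'   rel_diff_pct.
#' @export
compare_structures <- function(summaries) {
  stopifnot(length(summaries) >= 2)
  inc <- lapply(summaries, function(s) s$incremental$total)
  nm <- names(summaries)
  rows <- list()
  for (i in nm) for (j in setdiff(nm, i)) {
    for (metric in c("ly", "qaly")) {
      x <- inc[[i]][[metric]]; ref <- inc[[j]][[metric]]
      rows[[length(rows) + 1L]] <- data.frame(
        structure = i, reference = j, metric = metric,
        value = x, ref_value = ref,
        rel_diff_pct = if (ref == 0) NA_real_ else
          round_half_away(100 * (x - ref) / ref))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' One-way sensitivity analysis grid
#'
#' Re-evaluates the incremental outcomes of every structure varying one
#' dimension at a time from the base case: the time horizon (traces are
#' rebuilt), the annual discount rate, and named alternative utility
#' sets. The base case is included as the first rows.
#'
#' @param trace_builder Function `(horizon_days) -> named list of
#'   structures, each a list(A = trace, B = trace)`.
#' @param base_horizon_years Base-case horizon (default 7).
#' @param horizons_years Alternative horizons (default 5 and 10).
#' @param base_rate Base discount rate (default 0.045).
#' @param rates Alternative rates (default 3% and 7.5%).
#' @param utilities Base [utility_set()].
#' @param utility_alternatives Named list of alternative `utility_set`s.
#' @return Data frame: scenario, structure, inc_ly, inc_qaly.
#' @export
sensitivity_grid <- function(trace_builder, base_horizon_years = 7,
                             horizons_years = c(5, 10), base_rate = 0.045,
                             rates = c(0.03, 0.075),
                             utilities = utility_set(),
                             utility_alternatives = list()) {
  year <- 365.25
  eval_row <- function(scenario, traces, u, rate) {
    do.call(rbind, lapply(names(traces), function(st) {
      sm <- summarize_outcomes(traces[[st]]$A, traces[[st]]$B, u,
                               discount_spec(rate))
      data.frame(scenario = scenario, structure = st,
                 inc_ly = sm$incremental$total$ly,
                 inc_qaly = sm$incremental$total$qaly)
    }))
  }
  base_traces <- trace_builder(base_horizon_years * year)
  out <- list(eval_row("base", base_traces, utilities, base_rate))
  for (h in horizons_years) {
    out[[length(out) + 1L]] <- eval_row(sprintf("horizon_%gy", h),
                                        trace_builder(h * year),
                                        utilities, base_rate)
  }
  for (r in rates) {
    out[[length(out) + 1L]] <- eval_row(sprintf("rate_%g%%", 100 * r),
                                        base_traces, utilities, r)
  }
  for (nm in names(utility_alternatives)) {
    out[[length(out) + 1L]] <- eval_row(paste0("utility_", nm), base_traces,
                                        utility_alternatives[[nm]], base_rate)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
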