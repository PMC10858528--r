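test_that("conditional exit probability matches closed and quadrature forms", {
  m <- exp_model(0.003)
  # memorylessness: identical at every clock time
  q <- conditional_exit_probability(m, c(0, 100, 1000), 21)
  expect_equal(q, rep(1 - exp(-0.003 * 21), 3))
  # vanishing cycle length
  expect_lt(conditional_exit_probability(m, 50, 1e-8), 1e-9)
  # weibull against numerically integrated hazard
  w <- wei_model(2, 100)
  q_w <- conditional_exit_probability(w, 50, 21)
  cum_h <- stats::integrate(function(u) hazard_at(w, u), 50, 71,
                            rel.tol = 1e-12)$value
  expect_equal(q_w, 1 - exp(-cum_h), tolerance = 1e-10)
  # exhausted curve: everyone exits
  spent <- wei_model(3, 10)
  expect_equal(conditional_exit_probability(spent, 1000, 21), 1)
})

test_that("PSM trace reads occupancy off the curves", {
  os <- exp_model(0.002); tt <- exp_model(0.004)
  tr <- build_psm_trace(os, tt, horizon_days = 420, cycle_days = 21)
  expect_equal(unname(tr$occupancy[1, ]), c(1, 0, 0))
  i <- which(tr$time == 210)
  expect_equal(unname(tr$occupancy[i, "PP"]), exp(-0.42) - exp(-0.84))
  # coinciding curves leave no one in PP
  tr2 <- build_psm_trace(os, os, horizon_days = 420, cycle_days = 21)
  expect_true(all(tr2$occupancy[, "PP"] == 0))
  # crossing curves: PF capped at OS, PP floored at 0
  tr3 <- build_psm_trace(exp_model(0.004), exp_model(0.002),
                         horizon_days = 420, cycle_days = 21)
  expect_true(all(tr3$occupancy[, "PP"] >= 0))
  expect_gt(tr3$events[["crossing_cap"]], 0)
})

test_that("all-exponential 3-state trace equals the matrix-power oracle", {
  c. <- 21
  l_prog <- 0.002; l_dpf <- 0.001; l_dpp <- 0.003
  tr <- build_stm3_trace(exp_stm3_models(l_prog, l_dpf, l_dpp),
                         horizon_days = 2556.75, cycle_days = c.)
  # oracle rates: with exponential curves the engine's implied progression
  # probability is exactly 1 - exp(-l_prog * c)
  oracle <- matrix_power_trace(
    c("PF", "PP", "Death"),
    list(PF = c(PP = l_prog, Death = l_dpf), PP = c(Death = l_dpp)),
    c(PF = 1, PP = 0, Death = 0), length(tr$time) - 1L, c.)
  expect_lt(max(abs(tr$occupancy - oracle)), 1e-8)
})

test_that("zero death hazards keep the cohort alive", {
  mods <- list(ttnt = exp_model(0.004), death_from_pf = exp_model(0),
               death_from_pp = exp_model(0))
  tr <- build_stm3_trace(mods, horizon_days = 1000, cycle_days = 21)
  expect_true(all(tr$occupancy[, "Death"] == 0))
  n <- length(tr$time)
  expect_equal(tr$occupancy[, "PF"], exp(-0.004 * tr$time), tolerance = 1e-10)
})

test_that("traces conserve mass and death is monotone", {
  set.seed(42)
  for (i in 1:10) {
    rnd <- function() {
      if (stats::runif(1) < 0.5) exp_model(stats::runif(1, 1e-4, 5e-3))
      else wei_model(stats::runif(1, 0.7, 1.8), stats::runif(1, 150, 900))
    }
    m3 <- list(ttnt = rnd(), death_from_pf = rnd(), death_from_pp = rnd())
    m5 <- stats::setNames(replicate(8, rnd(), simplify = FALSE),
                          c("ttnt_from_pf", "death_from_pf", "bm_from_pf",
                            "death_from_pp", "bm_from_pp", "ttnt_in_bmit",
                            "death_in_bmit", "death_in_bmst"))
    for (tr in list(suppressWarnings(build_stm3_trace(m3, 1500, 21)),
                    suppressWarnings(build_stm5_trace(m5, stats::runif(1), 1500, 21)))) {
      expect_true(all(abs(rowSums(tr$occupancy) - 1) < 1e-9))
      expect_true(all(diff(tr$occupancy[, "Death"]) >= -1e-12))
      expect_true(all(tr$occupancy >= -1e-12))
      # tunnel decomposition adds up to the aggregate occupancy
      for (s in names(tr$tunnels)) {
        expect_equal(unname(rowSums(tr$tunnels[[s]])),
                     unname(tr$occupancy[, s]), tolerance = 1e-12)
      }
    }
  }
})

test_that("5-state engine collapses to the 3-state engine without brain metastasis", {
  l_prog <- 0.0025; l_dpf <- 0.0012; l_dpp <- 0.0031
  m5 <- exp_stm5_models(l_prog, l_dpf, 0, l_dpp, 0, 0, 0, 0.002)
  m3 <- exp_stm3_models(l_prog, l_dpf, l_dpp)
  t5 <- build_stm5_trace(m5, 0, 2556.75, 21)
  t3 <- build_stm3_trace(m3, 2556.75, 21)
  expect_lt(max(abs(t5$occupancy[, c("PF", "PP", "Death")] - t3$occupancy)),
            1e-12)
  expect_true(all(t5$occupancy[, c("BMIT", "BMST")] == 0))
})

test_that("whole cohort stays in BMIT when its exit hazards vanish", {
  m5 <- exp_stm5_models(0.002, 0.001, 0.0008, 0.003, 0.001, 0, 0, 0.002)
  t5 <- build_stm5_trace(m5, 1, 1000, 21)
  expect_true(all(t5$occupancy[, "BMIT"] == 1))
})

test_that("all-exponential 5-state trace equals the matrix-power oracle", {
  rates <- list(PF = c(PP = 0.0020, Death = 0.0008, BMIT = 0.0010),
                PP = c(Death = 0.0030, BMST = 0.0012),
                BMIT = c(BMST = 0.0025, Death = 0.0015),
                BMST = c(Death = 0.0040))
  m5 <- exp_stm5_models(0.0020, 0.0008, 0.0010, 0.0030, 0.0012,
                        0.0025, 0.0015, 0.0040)
  f <- 0.2
  t5 <- build_stm5_trace(m5, f, 2556.75, 21)
  oracle <- matrix_power_trace(c("PF", "PP", "BMIT", "BMST", "Death"), rates,
                               c(PF = 1 - f, PP = 0, BMIT = f, BMST = 0,
                                 Death = 0), length(t5$time) - 1L, 21)
  expect_lt(max(abs(t5$occupancy - oracle)), 1e-8)
})

test_that("PSM and 3-state traces agree to first order in the cycle length", {
  # mutually consistent exponential hazards: OS hazard = death hazard from
  # both alive states; TTNT hazard = total PF exit hazard
  l_p <- 0.003; l_d <- 0.0015
  m3 <- exp_stm3_models(l_p, l_d, l_d)
  gap <- function(c.) {
    t3 <- build_stm3_trace(m3, 2556.75, c.)
    ps <- build_psm_trace(exp_model(l_d), exp_model(l_p + l_d), 2556.75, c.)
    max(abs(t3$occupancy - ps$occupancy))
  }
  g21 <- gap(21); g105 <- gap(10.5)
  expect_lt(g21, 0.03)          # O(c): small at a 21-day cycle
  expect_gt(g21 / g105, 1.6)    # halving the cycle roughly halves the gap
  expect_lt(g21 / g105, 2.4)
})

test_that("microsimulation reproduces the cohort trace and is deterministic", {
  m3 <- exp_stm3_models(0.002, 0.001, 0.003)
  s3 <- stm3_structure(m3)
  tr <- build_stm3_trace(m3, 1000, 21)
  mi <- microsimulate(s3, n = 50000, seed = 77, horizon_days = 1000,
                      cycle_days = 21)
  bound <- 4 * sqrt(pmax(tr$occupancy * (1 - tr$occupancy), 1e-12) / 50000)
  expect_true(all(abs(mi$occupancy - tr$occupancy) <= pmax(bound, 4 / 50000)))
  mi2 <- microsimulate(s3, n = 50000, seed = 77, horizon_days = 1000,
                       cycle_days = 21)
  expect_identical(mi$occupancy, mi2$occupancy)
  # a single individual walks one valid path
  one <- microsimulate(s3, n = 1, seed = 5, horizon_days = 1000, cycle_days = 21)
  expect_true(all(rowSums(one$occupancy) == 1))
  expect_true(all(one$occupancy %in% c(0, 1)))
})

test_that("subtraction mode reproduces literal probability differencing", {
  m3 <- exp_stm3_models(0.002, 0.001, 0.003)
  tr <- build_stm3_trace(m3, 420, 21, competing = "subtraction")
  c. <- 21
  q_tot <- 1 - exp(-0.003 * c.)
  q2 <- 1 - exp(-0.001 * c.)
  # first cycle: PF sheds exactly q_tot, death takes exactly q2
  expect_equal(unname(tr$occupancy[2, "PF"]), 1 - q_tot, tolerance = 1e-12)
  expect_equal(unname(tr$occupancy[2, "Death"]), q2, tolerance = 1e-12)
  # inconsistent curves trip the progression floor warning
  bad <- list(ttnt = exp_model(0.0005), death_from_pf = exp_model(0.004),
              death_from_pp = exp_model(0.003))
  expect_warning(build_stm3_trace(bad, 420, 21), "inconsistent")
})
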