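test_that("transition matrix composes death first, then progression", {
  # zero-mortality limit: the NDR row is just stay/progress
  p0 <- dr_parameters(p_die = 0, mult_diabetes = 1, mult_blindness = 1)
  M0 <- build_transition_matrix(p0)
  expect_equal(unname(M0["NDR", ]), c(0.93, 0.07, 0, 0, 0, 0, 0))

  # base case: death 0.00707 * 2.34 resolved before progression
  M <- build_transition_matrix(dr_parameters())
  expect_equal(M["NDR", "NDR"], (1 - TBL_DEATH_NONBLIND) * 0.93,
               tolerance = 1e-12)
  expect_equal(M["NDR", "NDR"], 0.9146143, tolerance = 1e-7)
  expect_equal(M["NDR", "dead"], TBL_DEATH_NONBLIND)
  # blind state carries the extra blindness multiplier and cannot progress
  expect_equal(M["blindness", "dead"], 0.00707 * 2.34 * 1.9)
  expect_equal(sum(M["blindness", c("NDR", "mild_NPDR", "moderate_NPDR",
                                    "severe_NPDR", "PDR")]), 0)
  expect_equal(unname(M["dead", ]), c(0, 0, 0, 0, 0, 0, 1))
  expect_equal(unname(rowSums(M)), rep(1, 7), tolerance = 1e-12)
  expect_silent(validate_transition_matrix(M))

  # modifier 0 shuts progression off everywhere
  Mstop <- build_transition_matrix(dr_parameters(), modifier = rep(0, 5))
  off_diag <- Mstop
  diag(off_diag) <- 0
  off_diag[, 7] <- 0
  expect_true(all(off_diag == 0))

  expect_error(build_transition_matrix(dr_parameters(), modifier = rep(2, 5)),
               "modifier")
  expect_error(death_probabilities(dr_parameters(p_die = 0.5)), "exceeds 1")
})

test_that("alternative mortality wiring swaps the multiplier attachment", {
  d <- death_probabilities(dr_parameters(mortality_wiring = "blindness"))
  expect_equal(unname(d[1:5]), rep(0.00707 * 1.9, 5))
  expect_equal(unname(d[6]), 0.00707 * 1.9 * 2.34)
  # this wiring reproduces the 5-cycle cumulative death fraction of 6.5%
  M <- build_transition_matrix(dr_parameters(mortality_wiring = "blindness"))
  tr <- run_cohort_trace(M, initial_distribution(dr_parameters()), 5)
  expect_equal(round(tr[6, "dead"], 3), 0.065)
})

test_that("cohort traces conserve mass and propagate correctly", {
  # identity matrix: constant trace
  M_id <- diag(7)
  init <- c(0.5, 0.2, 0.1, 0.1, 0.05, 0.05, 0)
  tr <- run_cohort_trace(M_id, init, 10, cohort_size = 100)
  for (t in 1:11) expect_equal(unname(tr[t, ]), init * 100)

  # two-state toy chain against hand-multiplied matrix powers
  M <- diag(7)
  M[1, 1] <- 0.6; M[1, 2] <- 0.4
  M[2, 2] <- 0.9; M[2, 7] <- 0.1
  init2 <- c(1, rep(0, 6))
  tr2 <- run_cohort_trace(M, init2, 2)
  expect_equal(unname(tr2[2, 1:2]), c(0.6, 0.4))
  expect_equal(unname(tr2[3, 1:2]), c(0.36, 0.6 * 0.4 + 0.4 * 0.9))
  expect_equal(tr2[3, 7], 0.4 * 0.1)

  # conservation and monotone deaths for random treatment modifiers
  set.seed(42)
  for (rep in 1:10) {
    M <- build_transition_matrix(dr_parameters(), modifier = runif(5))
    tr <- run_cohort_trace(M, initial_distribution(dr_parameters(),
                                                   "prevalence"),
                           50, cohort_size = 10000)
    expect_equal(unname(rowSums(tr)), rep(10000, 51), tolerance = 1e-6)
    expect_true(all(tr >= 0))
    expect_true(all(diff(tr[, "dead"]) >= 0))
  }

  # with all death probabilities zero the dead state stays empty
  M <- build_transition_matrix(dr_parameters(p_die = 0, mult_diabetes = 1,
                                             mult_blindness = 1))
  tr <- run_cohort_trace(M, c(1, rep(0, 6)), 50)
  expect_equal(unname(tr[, "dead"]), rep(0, 51))

  expect_error(run_cohort_trace(matrix(0.5, 7, 7), c(1, rep(0, 6)), 5),
               "non-stochastic")
  expect_error(run_cohort_trace(diag(7), c(0.5, rep(0, 6)), 5), "sum to 1")
})

test_that("five-cycle survivors without DR match the conditional 0.93^5", {
  M <- build_transition_matrix(dr_parameters())
  tr <- run_cohort_trace(M, c(1, rep(0, 6)), 5)
  frac <- tr[6, "NDR"] / sum(tr[6, 1:6])
  expect_equal(frac, 0.93^5, tolerance = 1e-6)
  expect_equal(round(frac, 4), 0.6957)
})

test_that("new entrants equal explicit flows and conserve deaths", {
  expect_true(all(new_entrants(run_cohort_trace(diag(7), c(1, rep(0, 6)), 5),
                               diag(7)) == 0))

  M <- diag(7)
  M[1, 1] <- 0.7; M[1, 2] <- 0.2; M[1, 7] <- 0.1
  M[2, 2] <- 0.8; M[2, 7] <- 0.2
  tr <- run_cohort_trace(M, c(1, rep(0, 6)), 3)
  inflow2 <- new_entrants(tr, M, "mild_NPDR")
  expect_equal(unname(inflow2), c(0.2, 0.7 * 0.2, 0.49 * 0.2))
  # inflows never exceed the next-cycle occupancy of the state
  expect_true(all(inflow2 <= tr[-1, "mild_NPDR"] + 1e-12))
  # total inflow into dead equals the final death count
  expect_equal(sum(new_entrants(tr, M, "dead")), tr[4, "dead"])
})

test_that("accrual matches closed forms on single-state chains", {
  # one alive state, no death, no discounting: 50 undiscounted QALYs
  M <- diag(7)
  init <- c(1, rep(0, 6))
  u <- c(1, rep(0, 6))
  tr <- run_cohort_trace(M, init, 50)
  acc <- accrue_discounted_outcomes(tr, u, discount = 0, half_cycle = TRUE)
  expect_equal(acc$qalys, 50)

  # survival s per cycle, utility u, rate r, half-cycle off:
  # geometric sum u * sum_t s^t (1+r)^-t
  s <- 0.92; uu <- 0.85; r <- 0.04; n <- 30
  M[1, 1] <- s; M[1, 7] <- 1 - s
  tr <- run_cohort_trace(M, init, n)
  acc <- accrue_discounted_outcomes(tr, uu * u, discount = r,
                                    half_cycle = FALSE)
  expect_equal(acc$qalys, uu * sum((s / (1 + r))^(1:n)), tolerance = 1e-12)
})

test_that("half-cycle correction is a no-op on a constant undiscounted chain", {
  init <- c(0.3, 0.3, 0.2, 0.1, 0.05, 0.05, 0)
  tr <- run_cohort_trace(diag(7), init, 20)
  u <- c(0.9, 0.8, 0.8, 0.8, 0.7, 0.6, 0)
  on <- accrue_discounted_outcomes(tr, u, discount = 0, half_cycle = TRUE)
  off <- accrue_discounted_outcomes(tr, u, discount = 0, half_cycle = FALSE)
  expect_equal(on$qalys, off$qalys, tolerance = 1e-12)
})

test_that("raising the discount rate strictly lowers accrued rewards", {
  M <- build_transition_matrix(dr_parameters())
  tr <- run_cohort_trace(M, initial_distribution(dr_parameters()), 50)
  u <- utility_vector(dr_parameters())
  costs <- c(rep(10, 6), 0)
  rates <- c(0, 0.02, 0.04, 0.06)
  acc <- lapply(rates, function(r)
    accrue_discounted_outcomes(tr, u, state_costs = costs, discount = r))
  q <- vapply(acc, `[[`, 1, "qalys")
  cc <- vapply(acc, `[[`, 1, "cost")
  expect_true(all(diff(q) < 0))
  expect_true(all(diff(cc) < 0))
})

test_that("accrued rewards match a brute-force path-enumeration oracle", {
  set.seed(2024)
  for (rep in 1:6) {
    k <- sample(2:4, 1)
    n <- sample(3:6, 1)
    chain <- random_embedded_chain(k)
    u <- c(runif(k), rep(0, 7 - k))
    sc <- c(runif(k, 0, 5), rep(0, 7 - k))
    ec <- c(runif(k, 0, 3), rep(0, 7 - k))
    for (half in c(TRUE, FALSE)) {
      tr <- run_cohort_trace(chain$M, chain$init, n)
      got <- accrue_discounted_outcomes(tr, u, state_costs = sc,
                                        entry_costs = ec, discount = 0.03,
                                        half_cycle = half, M = chain$M)
      want <- oracle_accrue(chain$M, chain$init, n, u, sc, ec,
                            discount = 0.03, half_cycle = half)
      expect_equal(got$qalys, want$qalys, tolerance = 1e-9)
      expect_equal(got$cost, want$cost, tolerance = 1e-9)
    }
  }
})

test_that("accrual rejects negative rewards and missing matrices", {
  tr <- run_cohort_trace(diag(7), c(1, rep(0, 6)), 5)
  expect_error(accrue_discounted_outcomes(tr, c(-1, rep(0, 6))), "negative")
  expect_error(
    accrue_discounted_outcomes(tr, rep(0, 7),
                               entry_costs = c(1, rep(0, 6))),
    "'M' is required")
})

test_that("trace exports one row per cycle and state", {
  tr <- run_cohort_trace(diag(7), c(1, rep(0, 6)), 4, cohort_size = 10)
  df <- trace_as_data_frame(tr)
  expect_equal(nrow(df), 5 * 7)
  expect_equal(names(df), c("cycle", "state", "occupancy"))
  expect_equal(sum(df$occupancy), 5 * 10)
})
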