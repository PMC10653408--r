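test_that("blended progression mixes treated and untreated risk", {
  expect_equal(blended_progression(0.29, sens = 1, rr = 0.49), 0.1421)
  expect_equal(blended_progression(0.29, sens = 0, rr = 0.49), 0.29)
  expect_equal(blended_progression(0.17, sens = 0.7, rr = 1), 0.17)
  # linear in sens between the two extremes
  expect_equal(blended_progression(0.2, 0.5, 0.4),
               0.5 * 0.08 + 0.5 * 0.2)
  expect_error(blended_progression(0.2, 0.5, 0), "rr")
})

test_that("the no-screening arm carries no costs and pure natural history", {
  params <- dr_parameters()
  none <- assemble_strategy(params, dr_strategy("none"))
  expect_equal(none$M, build_transition_matrix(params))
  expect_equal(unname(none$per_cycle), rep(0, 7))
  expect_equal(unname(none$entry), rep(0, 7))
})

test_that("screened-arm cost schedules follow the published unit costs", {
  strategies <- default_strategies()
  costs_ai <- per_cycle_state_costs(strategies$ai)

  # every alive state pays screening + transport: 25.01 + 2.74 RMB
  base <- costs_ai$per_cycle[["NDR"]] # no false positives removed yet
  fp <- (1 - 0.985) * (610.2 + 17.8)
  expect_equal(base - fp, 25.01 + 2.74, tolerance = 2e-3)
  expect_equal(costs_ai$per_cycle[["blindness"]], base - fp)
  # referable states add the sensitivity-weighted work-up
  expect_equal(costs_ai$per_cycle[["severe_NPDR"]],
               base - fp + 0.9079 * (610.2 + 17.8), tolerance = 1e-9)
  # dead costs nothing
  expect_equal(costs_ai$per_cycle[["dead"]], 0)
  # laser on entry, weighted by the detection rate
  expect_equal(costs_ai$entry[["severe_NPDR"]],
               0.3259 * convert_currency(424.41, "USD"))
  expect_equal(costs_ai$entry[["PDR"]], costs_ai$entry[["severe_NPDR"]])

  # perfect specificity removes the false-positive charge
  perfect <- dr_strategy("ai", sensitivity = 0.9, specificity = 1,
                         detection = 0.3, followup_cost = 610.2,
                         hospital_transport = 17.8, screening_cost = 25)
  cp <- per_cycle_state_costs(perfect)
  expect_equal(cp$per_cycle[["NDR"]], 25)

  # vitrectomy option adds to the PDR entry cost only
  vit <- dr_strategy("ai", sensitivity = 0.9, detection = 0.3,
                     laser_cost = 3051.3, vitrectomy_cost = 11841,
                     include_vitrectomy = TRUE)
  cv <- per_cycle_state_costs(vit)
  expect_equal(cv$entry[["PDR"]] - cv$entry[["severe_NPDR"]],
               0.3 * 11841)

  # per-cycle treatment timing moves the laser cost into the state costs
  ann <- dr_strategy("ai", sensitivity = 0.9, detection = 0.3,
                     laser_cost = 1000, treatment_timing = "per_cycle")
  ca <- per_cycle_state_costs(ann)
  expect_equal(unname(ca$entry), rep(0, 7))
  expect_equal(ca$per_cycle[["severe_NPDR"]], 0.3 * 1000)
})

test_that("treatment lowers progression out of the treated states only", {
  params <- dr_parameters()
  arms <- lapply(default_strategies(), assemble_strategy, params = params)
  M_none <- arms$none$M
  M_ai <- arms$ai$M
  expect_lt(M_ai["severe_NPDR", "PDR"], M_none["severe_NPDR", "PDR"])
  expect_lt(M_ai["PDR", "blindness"], M_none["PDR", "blindness"])
  expect_equal(M_ai["NDR", ], M_none["NDR", ])
  expect_equal(M_ai["moderate_NPDR", ], M_none["moderate_NPDR", ])
  for (arm in arms) expect_silent(validate_transition_matrix(arm$M))
})

test_that("ineffective screening collapses every arm onto natural history", {
  params <- dr_parameters()
  init <- initial_distribution(params, "prevalence")
  tr_none <- run_cohort_trace(build_transition_matrix(params), init, 50)

  for (strat in list(
    dr_strategy("ai", sensitivity = 0, detection = 0, rr_laser = 0.49),
    dr_strategy("ai", sensitivity = 0.9, detection = 0.33, rr_laser = 1),
    dr_strategy("ophthalmologist", sensitivity = 0.96, detection = 0.17,
                rr_laser = 1, uptake = "sensitivity")
  )) {
    arm <- assemble_strategy(params, strat)
    tr <- run_cohort_trace(arm$M, init, 50)
    expect_equal(unclass(tr), unclass(tr_none))
  }
})

test_that("screening never increases cumulative blindness incidence", {
  # Treatment only reduces progression, so cumulative entries into the
  # blind state can never exceed natural history at any cycle. Point
  # occupancy CAN cross very late in the horizon (entries arrive later
  # under treatment and have had less time to die off), which is why the
  # invariant is on incidence, not occupancy.
  params <- dr_parameters()
  init <- initial_distribution(params, "prevalence")
  M_none <- build_transition_matrix(params)
  tr_none <- run_cohort_trace(M_none, init, 50)
  blind_inc_none <- cumsum(new_entrants(tr_none, M_none, "blindness"))
  for (strat in default_strategies()[c("ai", "ophthalmologist")]) {
    arm <- assemble_strategy(params, strat)
    tr <- run_cohort_trace(arm$M, init, 50)
    blind_inc <- cumsum(new_entrants(tr, arm$M, "blindness"))
    expect_true(all(blind_inc <= blind_inc_none + 1e-12))
    # occupancy is still lower over the first half of the horizon
    expect_true(all(tr[1:26, "blindness"] <=
                      tr_none[1:26, "blindness"] + 1e-12))
  }
})

test_that("treatment uptake can be keyed to sensitivity instead", {
  params <- dr_parameters()
  s_det <- dr_strategy("ai", sensitivity = 0.9079, detection = 0.3259,
                       uptake = "detection")
  s_sen <- dr_strategy("ai", sensitivity = 0.9079, detection = 0.3259,
                       uptake = "sensitivity")
  M_det <- assemble_strategy(params, s_det)$M
  M_sen <- assemble_strategy(params, s_sen)$M
  expect_equal(M_det["severe_NPDR", "PDR"] /
                 (1 - TBL_DEATH_NONBLIND),
               blended_progression(0.29, 0.3259, 0.49))
  expect_equal(M_sen["severe_NPDR", "PDR"] /
                 (1 - TBL_DEATH_NONBLIND),
               blended_progression(0.29, 0.9079, 0.49))
  # higher uptake, stronger protection
  expect_lt(M_sen["severe_NPDR", "PDR"], M_det["severe_NPDR", "PDR"])
})
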