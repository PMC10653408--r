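test_that("parameter distributions honour their closed-form parameterization", {
  # fixed family: point mass
  fx <- parameter_distribution(param_spec("x", 2, 1, 3, "fixed", "p"))
  expect_equal(fx(5), rep(2, 5))

  # lognormal for the laser relative risk: median at base,
  # sigma = (log(high) - log(low)) / 3.92
  rr <- param_spec("rr", 0.49, 0.37, 0.64, "lognormal", "p")
  expect_equal((log(0.64) - log(0.37)) / 3.92, 0.1398, tolerance = 1e-4)
  draws <- with_seed_test(1, parameter_distribution(rr)(1e5))
  expect_equal(median(draws), 0.49, tolerance = 0.01)
  expect_equal(sd(log(draws)), 0.1398, tolerance = 0.01)

  # beta with mean 0.07 and a +/-25% range: sample mean within 1%
  be <- param_spec("p", 0.07, 0.0525, 0.0875, "beta", "p")
  draws <- with_seed_test(2, parameter_distribution(be)(1e5))
  expect_equal(mean(draws), 0.07, tolerance = 0.01)
  expect_true(all(draws >= 0 & draws <= 1))

  # gamma for costs: mean at base, sd from the +/-50% range
  ga <- param_spec("c", 610.2, 305.1, 915.3, "gamma", "p")
  draws <- with_seed_test(3, parameter_distribution(ga)(1e5))
  expect_equal(mean(draws), 610.2, tolerance = 0.01 * 610.2)
  expect_equal(sd(draws), (915.3 - 305.1) / 3.92, tolerance = 0.02 * 155.7)

  # utilities with ranges above 1 are rescaled and truncated
  expect_warning(
    tr <- parameter_distribution(param_spec("u", 0.94, 0.83, 1.05,
                                            "beta", "p")),
    "truncating")
  draws <- with_seed_test(4, tr(1e4))
  expect_true(all(draws <= 1))

  expect_error(param_spec("bad", 5, 1, 4, "beta", "p"), "low <= base")
})

test_that("PSA is reproducible and its substreams are independent", {
  cfg <- dr_config(n_cycles = 10)
  specs <- default_psa_specs(cfg)
  p1 <- suppressWarnings(run_psa(cfg, specs, n_draws = 40, seed = 5))
  p2 <- suppressWarnings(run_psa(cfg, specs, n_draws = 40, seed = 5))
  expect_identical(p1, p2)
  p3 <- suppressWarnings(run_psa(cfg, specs, n_draws = 40, seed = 6))
  expect_false(identical(p1$cost_ai, p3$cost_ai))

  # dropping a parameter leaves every other parameter's draws untouched
  sub <- specs[setdiff(names(specs), "u_NDR")]
  p4 <- suppressWarnings(run_psa(cfg, sub, n_draws = 40, seed = 5))
  for (nm in names(sub)) expect_identical(p1[[nm]], p4[[nm]])
})

test_that("an all-fixed specification reproduces the base case", {
  cfg <- dr_config(n_cycles = 25)
  base <- retscreen:::evaluate_outcomes(cfg)
  specs <- list(param_spec("rr", 0.49, 0.49, 0.49, "fixed",
                           c("strategies/ai/rr_laser",
                             "strategies/ophthalmologist/rr_laser")))
  psa <- run_psa(cfg, specs, n_draws = 3, seed = 1)
  for (nm in c("none", "ai", "ophthalmologist")) {
    expect_equal(psa[[paste0("cost_", nm)]],
                 rep(base$cost[base$label == nm], 3))
    expect_equal(psa[[paste0("qalys_", nm)]],
                 rep(base$qalys[base$label == nm], 3))
  }
})

test_that("CEAC probabilities are coherent and converge at the limits", {
  cfg <- dr_config(n_cycles = 10)
  psa <- suppressWarnings(run_psa(cfg, n_draws = 150, seed = 3))
  grid <- seq(0, 400000, length.out = 9)
  cc <- ceac(psa, grid)
  sums <- tapply(cc$probability, cc$wtp, sum)
  expect_equal(as.vector(sums), rep(1, length(grid)), tolerance = 1e-9)
  expect_true(all(cc$probability >= 0 & cc$probability <= 1))

  # at wtp -> infinity the mass sits on the highest-effect strategy per draw
  huge <- ceac(psa, 1e12)
  eff <- as.matrix(psa[, paste0("qalys_", attr(psa, "strategies"))])
  best <- table(factor(attr(psa, "strategies")[apply(eff, 1, which.max)],
                       levels = attr(psa, "strategies"))) / nrow(psa)
  expect_equal(huge$probability, unname(as.vector(best)), tolerance = 1e-9)

  # a single-strategy PSA is certainly cost-effective
  cfg1 <- dr_config(strategies = list(none = dr_strategy("none")),
                    n_cycles = 10)
  specs1 <- default_psa_specs(cfg1)
  psa1 <- suppressWarnings(run_psa(cfg1, specs1, n_draws = 20, seed = 2))
  cc1 <- ceac(psa1, c(0, 1e5))
  expect_equal(cc1$probability, c(1, 1))
})

test_that("tornado bars reflect one-way parameter influence", {
  cfg <- dr_config(n_cycles = 15)
  specs <- list(
    # a parameter with no influence under the all-NDR start
    param_spec("prev_NDR", 0.6254, 0.75 * 0.6254, 1.25 * 0.6254, "beta",
               "params/prevalence/NDR"),
    param_spec("discount", 0.03, 0, 0.06, "uniform", "params/discount"),
    param_spec("rr_laser", 0.49, 0.37, 0.64, "lognormal",
               c("strategies/ai/rr_laser",
                 "strategies/ophthalmologist/rr_laser")),
    # zero-width range
    param_spec("p_die", 0.00707, 0.00707, 0.00707, "beta",
               "params/p_die")
  )
  tor <- one_way_tornado(cfg, specs)
  expect_equal(tor$width[tor$parameter == "prev_NDR"], 0)
  expect_equal(tor$width[tor$parameter == "p_die"], 0)
  expect_gt(tor$width[tor$parameter == "discount"], 0)
  # bars are sorted by width and endpoints equal a direct evaluation
  expect_true(!is.unsorted(rev(tor$width)))
  cfg_lo <- cfg
  cfg_lo$params$discount <- 0
  out_lo <- retscreen:::evaluate_outcomes(retscreen:::rebuild_config(cfg_lo))
  direct <- icer(as.list(out_lo[out_lo$label == "ai", ]),
                 as.list(out_lo[out_lo$label == "none", ]))
  expect_equal(tor$icer_low[tor$parameter == "discount"], direct$ratio)
})

test_that("invalid draws are rejected and deterministically repaired", {
  cfg <- dr_config(n_cycles = 5)
  # a blindness multiplier whose distribution dips below 1 regularly
  specs <- list(param_spec("mult_blindness", 1.05, 0.6, 1.8, "lognormal",
                           "params/mult_blindness"))
  psa <- run_psa(cfg, specs, n_draws = 60, seed = 4)
  expect_gt(attr(psa, "n_rejected"), 0)
  expect_true(all(psa$mult_blindness >= 1))
  psa2 <- run_psa(cfg, specs, n_draws = 60, seed = 4)
  expect_identical(psa, psa2)
})

test_that("simulate() on a fit runs the PSA at the fit's configuration", {
  fit <- dr_cea(n_cycles = 10)
  psa <- suppressWarnings(simulate(fit, nsim = 25, seed = 9))
  expect_s3_class(psa, "dr_psa")
  expect_equal(nrow(psa), 25)
  expect_equal(attr(psa, "strategies"), names(fit$strategies))
})
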