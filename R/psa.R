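#' Declare an uncertain model parameter
#'
#' A parameter specification for sensitivity analysis: its base value,
#' uncertainty range, distribution family, and the place(s) in the
#' analysis configuration it feeds. A single specification may point at
#' several configuration paths (e.g. a unit cost shared by both screened
#' arms) so that one draw moves them jointly.
#'
#' Families follow health-economics convention: probabilities and
#' utilities are beta, costs gamma, relative risks lognormal; the
#' discount rate is swept uniformly. Beta and gamma are parameterized by
#' the method of moments from the base value as mean and
#' `(high - low) / (2 * 1.96)` as standard deviation (the range read as
#' a 95% interval); the lognormal takes the base as median with
#' `sigma = (log(high) - log(low)) / (2 * 1.96)`.
#'
#' @param name Parameter name (also the RNG substream key).
#' @param base Base-case value; `low <= base <= high` required.
#' @param low,high Range swept in one-way analysis / informing the
#'   distribution.
#' @param family `"beta"`, `"gamma"`, `"lognormal"`, `"uniform"` or
#'   `"fixed"`.
#' @param paths Character vector of `/`-separated configuration paths,
#'   e.g. `"params/progression/no_to_mild"` or
#'   `"strategies/ai/detection"`.
#' @return A `param_spec` object.
#' @export
param_spec <- function(name, base, low, high,
                       family = c("beta", "gamma", "lognormal",
                                  "uniform", "fixed"),
                       paths) {
  family <- match.arg(family)
  if (!(low <= base && base <= high)) {
    stop("need low <= base <= high for parameter ", name)
  }
  if (family == "lognormal" && low <= 0) {
    stop("lognormal parameter must have positive bounds: ", name)
  }
  structure(list(name = name, base = base, low = low, high = high,
                 family = family, paths = paths),
            class = "param_spec")
}

#' Build the sampler of a parameter specification
#'
#' @param spec A [param_spec()].
#' @return A function of `n` returning `n` random draws from the
#'   parameter's distribution (a point mass at the base value for
#'   `"fixed"` specs or degenerate ranges). Beta specifications for
#'   utilities whose published range exceeds 1 are sampled on the
#'   rescaled support `[0, high]` and truncated to `[0, 1]`, with a
#'   warning at construction.
#' @export
parameter_distribution <- function(spec) {
  base <- spec$base
  sd <- (spec$high - spec$low) / (2 * 1.96)
  if (spec$family == "fixed" || sd == 0 || base == 0) {
    return(function(n) rep(base, n))
  }
  switch(spec$family,
    beta = {
      scale <- 1
      if (spec$high > 1) {
        warning("beta parameter '", spec$name,
                "' has range above 1; sampling on [0, ", spec$high,
                "] and truncating to [0, 1]", call. = FALSE)
        scale <- spec$high
      }
      m <- base / scale
      v <- (sd / scale)^2
      if (v >= m * (1 - m)) {
        stop("beta moment matching impossible for ", spec$name)
      }
      k <- m * (1 - m) / v - 1
      function(n) pmin(stats::rbeta(n, m * k, (1 - m) * k) * scale, 1)
    },
    gamma = {
      shape <- (base / sd)^2
      function(n) stats::rgamma(n, shape = shape, rate = base / sd^2)
    },
    lognormal = {
      sdlog <- (log(spec$high) - log(spec$low)) / (2 * 1.96)
      function(n) stats::rlnorm(n, meanlog = log(base), sdlog = sdlog)
    },
    uniform = function(n) stats::runif(n, spec$low, spec$high)
  )
}

# deterministic per-parameter RNG substream: a draw for parameter X does
# not depend on which other parameters are in the spec list
hash_name <- function(name) {
  h <- 0
  for (x in utf8ToInt(name)) h <- (h * 31 + x) %% 2147483647
  h
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

param_stream_seed <- function(root, name, salt = 0) {
  (hash_name(name) + root * 7919 + salt * 104729) %% 2147483647
}

set_path <- function(config, path, value) {
  keys <- strsplit(path, "/", fixed = TRUE)[[1]]
  expr <- config
  # recursive assignment via [[<- chain
  assign_rec <- function(x, keys, value) {
    if (!keys[1] %in% names(x)) {
      stop("unknown configuration path element '", keys[1], "'")
    }
    if (length(keys) == 1L) {
      x[[keys[1]]] <- value
    } else {
      x[[keys[1]]] <- assign_rec(x[[keys[1]]], keys[-1], value)
    }
    x
  }
  assign_rec(config, keys, value)
}

apply_draw <- function(config, specs, values) {
  for (k in seq_along(specs)) {
    for (p in specs[[k]]$paths) {
      config <- set_path(config, p, values[[k]])
    }
  }
  # joint behaviour of independently perturbed prevalence entries
  config$params$prevalence <- config$params$prevalence /
    sum(config$params$prevalence)
  rebuild_config(config)
}

#' Default sensitivity-analysis parameter set
#'
#' Encodes the study's uncertainty ranges: +/-25% for DR prevalence, the
#' positive detection rates and the annual transition probabilities
#' (beta); +/-50% for costs (gamma); published 95% confidence intervals
#' for the utilities (beta), screening sensitivity/specificity (beta),
#' the laser relative risk (lognormal) and the mortality multipliers
#' (lognormal); and 0-6% for the discount rate (uniform). Base values
#' are taken from `config` so that non-default configurations sweep
#' around their own base case.
#'
#' @param config A [dr_config()].
#' @return Named list of [param_spec()]s.
#' @export
default_psa_specs <- function(config = dr_config()) {
  p <- config$params
  specs <- list()
  add <- function(name, base, low, high, family, paths) {
    specs[[name]] <<- param_spec(name, base, low, high, family, paths)
  }
  pm25 <- function(x) c(0.75 * x, 1.25 * x)

  for (nm in names(p$prevalence)) {
    b <- p$prevalence[[nm]]
    add(paste0("prev_", nm), b, pm25(b)[1], pm25(b)[2], "beta",
        paste0("params/prevalence/", nm))
  }
  for (nm in names(p$progression)) {
    b <- p$progression[[nm]]
    add(paste0("p_", nm), b, pm25(b)[1], pm25(b)[2], "beta",
        paste0("params/progression/", nm))
  }
  add("p_die", p$p_die, pm25(p$p_die)[1], pm25(p$p_die)[2], "beta",
      "params/p_die")
  add("mult_diabetes", p$mult_diabetes, 2.22, 2.46, "lognormal",
      "params/mult_diabetes")
  add("mult_blindness", p$mult_blindness, 1.04, 2.7, "lognormal",
      "params/mult_blindness")
  add("u_NDR", p$utilities[["NDR"]], 0.83, 1.05, "beta",
      "params/utilities/NDR")
  add("u_NPDR", p$utilities[["NPDR"]], 0.73, 1.01, "beta",
      "params/utilities/NPDR")
  add("u_PDR", p$utilities[["PDR"]], 0.74, 0.92, "beta",
      "params/utilities/PDR")
  add("u_blindness", p$utilities[["blindness"]], 0.73, 0.89, "beta",
      "params/utilities/blindness")
  add("discount", p$discount, 0, 0.06, "uniform", "params/discount")

  screened <- names(config$strategies)[
    vapply(config$strategies, function(s) s$kind != "none", TRUE)]
  if (length(screened)) {
    s1 <- config$strategies[[screened[1]]]
    add("rr_laser", s1$rr_laser, 0.37, 0.64, "lognormal",
        paste0("strategies/", screened, "/rr_laser"))
    for (cost in c("screening_transport", "followup_cost",
                   "hospital_transport", "laser_cost",
                   "vitrectomy_cost")) {
      b <- s1[[cost]]
      add(paste0("c_", sub("_cost$", "", cost)), b, 0.5 * b, 1.5 * b,
          "gamma", paste0("strategies/", screened, "/", cost))
    }
  }
  ci <- list(ai = list(sen = c(0.8640, 0.9410), spe = c(0.978, 0.990)),
             ophthalmologist = list(sen = c(0.9479, 0.9721),
                                    spe = c(0.9457, 0.9743)))
  for (nm in screened) {
    s <- config$strategies[[nm]]
    b <- s$detection
    add(paste0("det_", nm), b, pm25(b)[1], pm25(b)[2], "beta",
        paste0("strategies/", nm, "/detection"))
    add(paste0("c_screening_", nm), s$screening_cost,
        0.5 * s$screening_cost, 1.5 * s$screening_cost, "gamma",
        paste0("strategies/", nm, "/screening_cost"))
    if (nm %in% names(ci)) {
      add(paste0("sen_", nm), s$sensitivity, ci[[nm]]$sen[1],
          ci[[nm]]$sen[2], "beta", paste0("strategies/", nm, "/sensitivity"))
      add(paste0("spe_", nm), s$specificity, ci[[nm]]$spe[1],
          ci[[nm]]$spe[2], "beta", paste0("strategies/", nm, "/specificity"))
    }
  }
  specs
}

#' One-way (tornado) sensitivity analysis
#'
#' Re-runs the full model with each parameter at its lower and upper
#' bound (all others at base) and records the ICER of the comparator
#' pair, sorted by bar width. Runs in which the comparison degenerates
#' (zero effect difference or dominance) carry the verdict alongside
#' the raw ratio.
#'
#' @param config A [dr_config()].
#' @param specs List of [param_spec()]s; defaults to the study's set.
#' @param comparators Length-2 character vector: the strategy evaluated
#'   and its reference (default AI vs no screening).
#' @return A `dr_tornado` data frame: `parameter`, `icer_low`,
#'   `icer_high`, `verdict_low`, `verdict_high`, `width`, sorted by
#'   descending width; attribute `base_icer`.
#' @export
one_way_tornado <- function(config = dr_config(),
                            specs = default_psa_specs(config),
                            comparators = c("ai", "none")) {
  stopifnot(all(comparators %in% names(config$strategies)))
  eval_icer <- function(cfg) {
    out <- evaluate_outcomes(cfg)
    icer(as.list(out[out$label == comparators[1], ]),
         as.list(out[out$label == comparators[2], ]))
  }
  base <- eval_icer(config)
  rows <- lapply(specs, function(sp) {
    lo <- eval_icer(apply_draw(config, list(sp), sp$low))
    hi <- eval_icer(apply_draw(config, list(sp), sp$high))
    data.frame(parameter = sp$name,
               icer_low = lo$ratio, icer_high = hi$ratio,
               verdict_low = lo$verdict, verdict_high = hi$verdict,
               width = abs(hi$ratio - lo$ratio),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$width), ]
  rownames(out) <- NULL
  structure(out, class = c("dr_tornado", "data.frame"),
            base_icer = base$ratio, comparators = comparators)
}

#' @export
plot.dr_tornado <- function(x, top = 12, ...) {
  d <- utils::head(x[!is.na(x$width), ], top)
  d <- d[rev(seq_len(nrow(d))), ]
  base <- attr(x, "base_icer")
  lo <- pmin(d$icer_low, d$icer_high)
  hi <- pmax(d$icer_low, d$icer_high)
  graphics::plot(NULL, xlim = range(c(lo, hi, base)),
                 ylim = c(0.5, nrow(d) + 0.5),
                 yaxt = "n", xlab = "ICER (RMB/QALY)", ylab = "",
                 main = "One-way sensitivity analysis", ...)
  graphics::axis(2, at = seq_len(nrow(d)), labels = d$parameter,
                 las = 1, cex.axis = 0.7)
  graphics::rect(lo, seq_len(nrow(d)) - 0.35, hi,
                 seq_len(nrow(d)) + 0.35, col = "steelblue")
  graphics::abline(v = base, lty = 2)
  invisible(x)
}

#' Probabilistic sensitivity analysis (Monte Carlo)
#'
#' Draws every non-fixed parameter from its distribution, rebuilds all
#' strategy arms, and accrues discounted outcomes per draw. Each
#' parameter owns an independent RNG substream derived from the root
#' seed, so adding or removing a parameter does not perturb the others'
#' draws, and identical seeds reproduce identical output. Draws whose
#' sampled values violate a model invariant (e.g. a mortality
#' multiplier below 1) are rejected and resampled deterministically;
#' the count is reported in the `n_rejected` attribute.
#'
#' @param config A [dr_config()].
#' @param specs List of [param_spec()]s.
#' @param n_draws Number of Monte Carlo samples (the study uses 10,000).
#' @param seed Root seed.
#' @return A `dr_psa` data frame: `draw`, one column per parameter, and
#'   `cost_<strategy>` / `qalys_<strategy>` columns; attributes `seed`,
#'   `n_rejected`, `strategies`.
#' @export
run_psa <- function(config = dr_config(),
                    specs = default_psa_specs(config),
                    n_draws = 1000, seed = 1) {
  stopifnot(n_draws >= 1)
  samplers <- lapply(specs, parameter_distribution)
  values <- matrix(NA_real_, n_draws, length(specs),
                   dimnames = list(NULL, vapply(specs, `[[`, "", "name")))
  for (k in seq_along(specs)) {
    values[, k] <- with_seed(param_stream_seed(seed, specs[[k]]$name),
                             samplers[[k]](n_draws))
  }

  strat_names <- names(config$strategies)
  cost <- matrix(NA_real_, n_draws, length(strat_names),
                 dimnames = list(NULL, strat_names))
  qalys <- cost
  n_rejected <- 0L
  for (i in seq_len(n_draws)) {
    attempt <- 0L
    repeat {
      out <- tryCatch(
        evaluate_outcomes(apply_draw(config, specs, values[i, ])),
        error = function(e) NULL
      )
      if (!is.null(out)) break
      n_rejected <- n_rejected + 1L
      attempt <- attempt + 1L
      if (attempt > 100L) stop("draw ", i, " could not be repaired")
      values[i, ] <- with_seed(
        param_stream_seed(seed, "rejection-repair", salt = i * 131L + attempt),
        vapply(samplers, function(s) s(1), numeric(1))
      )
    }
    cost[i, ] <- out$cost[match(strat_names, out$label)]
    qalys[i, ] <- out$qalys[match(strat_names, out$label)]
  }
  colnames(cost) <- paste0("cost_", strat_names)
  colnames(qalys) <- paste0("qalys_", strat_names)
  res <- data.frame(draw = seq_len(n_draws), values, cost, qalys,
                    check.names = FALSE)
  structure(res, class = c("dr_psa", "data.frame"),
            seed = seed, n_rejected = n_rejected, strategies = strat_names)
}

#' Probabilistic sensitivity analysis of a fitted model
#'
#' `simulate()` on a [dr_cea()] fit runs [run_psa()] over the fit's own
#' parameter and strategy configuration.
#'
#' @param object A `dr_cea` fit.
#' @param nsim Number of draws.
#' @param seed Root seed (required for reproducibility).
#' @param specs Optional list of [param_spec()]s.
#' @param ... Unused.
#' @return A `dr_psa` data frame; see [run_psa()].
#' @export
simulate.dr_cea <- function(object, nsim = 1000, seed = 1, specs = NULL, ...) {
  config <- dr_config(params = object$params,
                      strategies = object$strategies,
                      n_cycles = object$settings$n_cycles,
                      cohort_size = object$settings$cohort_size,
                      half_cycle = object$settings$half_cycle,
                      init = object$settings$init,
                      gdp = object$settings$gdp)
  if (is.null(specs)) specs <- default_psa_specs(config)
  run_psa(config, specs, n_draws = nsim, seed = seed)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the probability that each strategy
#' is cost-effective: the fraction of PSA draws in which it attains the
#' maximal net monetary benefit `E * wtp - C` (exact ties split evenly).
#'
#' @param psa A [run_psa()] result.
#' @param wtp_grid Numeric vector of willingness-to-pay values (RMB per
#'   QALY).
#' @return A `dr_ceac` data frame with columns `wtp`, `strategy`,
#'   `probability`; probabilities sum to 1 at every grid point.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 250000, by = 10000)) {
  stopifnot(nrow(psa) >= 1, length(wtp_grid) >= 1)
  strat <- attr(psa, "strategies")
  cost <- as.matrix(psa[, paste0("cost_", strat), drop = FALSE])
  eff <- as.matrix(psa[, paste0("qalys_", strat), drop = FALSE])
  rows <- lapply(wtp_grid, function(w) {
    nmb <- eff * w - cost
    best <- nmb == apply(nmb, 1, max)
    share <- best / rowSums(best)   # ties split evenly
    data.frame(wtp = w, strategy = strat,
               probability = colMeans(share), row.names = NULL,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("dr_ceac", "data.frame"))
}

#' @export
plot.dr_ceac <- function(x, ...) {
  strat <- unique(x$strategy)
  cols <- grDevices::hcl.colors(length(strat), "Dark 3")
  graphics::plot(NULL, xlim = range(x$wtp), ylim = c(0, 1),
                 xlab = "Willingness to pay (RMB/QALY)",
                 ylab = "Probability cost-effective",
                 main = "Cost-effectiveness acceptability curves", ...)
  for (i in seq_along(strat)) {
    d <- x[x$strategy == strat[i], ]
    graphics::lines(d$wtp, d$probability, col = cols[i], lwd = 2)
  }
  graphics::legend("right", legend = strat, col = cols, lwd = 2, bty = "n")
  invisible(x)
}
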