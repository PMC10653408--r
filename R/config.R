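#' Full analysis configuration
#'
#' Collects everything one model run needs: natural-history parameters,
#' the strategy arms, run options (horizon, cohort size, half-cycle
#' correction, initial distribution) and the willingness-to-pay
#' settings. The default configuration reproduces the study's base
#' case.
#'
#' @param params A [dr_parameters()] object.
#' @param strategies Named list of [dr_strategy()] arms.
#' @param n_cycles Model horizon in years.
#' @param cohort_size Cohort head count.
#' @param half_cycle Apply the half-cycle correction.
#' @param init `"ndr"` or `"prevalence"` initial distribution.
#' @param gdp Per-capita GDP (RMB) for WTP thresholds.
#' @param wtp_multipliers Threshold multipliers.
#' @param seed Default seed for stochastic analyses.
#' @return A `dr_config` object.
#' @export
dr_config <- function(params = dr_parameters(),
                      strategies = default_strategies(),
                      n_cycles = 50L, cohort_size = 10000,
                      half_cycle = TRUE, init = c("ndr", "prevalence"),
                      gdp = 72447, wtp_multipliers = 1:3, seed = 1L) {
  init <- match.arg(init)
  stopifnot(inherits(params, "dr_params"),
            all(vapply(strategies, inherits, TRUE, "dr_strategy")),
            n_cycles >= 1, cohort_size > 0)
  if (is.null(names(strategies))) {
    names(strategies) <- vapply(strategies, `[[`, "", "kind")
  }
  structure(
    list(params = params, strategies = strategies,
         run = list(n_cycles = as.integer(n_cycles),
                    cohort_size = cohort_size,
                    half_cycle = isTRUE(half_cycle), init = init,
                    seed = as.integer(seed)),
         wtp = list(gdp = gdp, multipliers = wtp_multipliers)),
    class = "dr_config"
  )
}

# revalidate a configuration whose leaves were modified in place
# (sensitivity analysis): reconstruct each component through its
# constructor so invariants are re-checked
rebuild_config <- function(config) {
  p <- unclass(config$params)
  params <- dr_parameters(progression = p$progression,
                          prevalence = p$prevalence, p_die = p$p_die,
                          mult_diabetes = p$mult_diabetes,
                          mult_blindness = p$mult_blindness,
                          mortality_wiring = p$mortality_wiring,
                          utilities = p$utilities, discount = p$discount)
  strategies <- lapply(config$strategies, function(s) {
    s <- unclass(s)
    s$treated_states <- unlist(s$treated_states)
    do.call(dr_strategy, s)
  })
  dr_config(params = params, strategies = strategies,
            n_cycles = config$run$n_cycles,
            cohort_size = config$run$cohort_size,
            half_cycle = config$run$half_cycle, init = config$run$init,
            gdp = config$wtp$gdp, wtp_multipliers = config$wtp$multipliers,
            seed = config$run$seed)
}

# per-strategy discounted per-capita outcomes for a configuration;
# the inner loop of the PSA, kept free of object overhead
evaluate_outcomes <- function(config) {
  params <- config$params
  init_vec <- initial_distribution(params, config$run$init)
  u <- utility_vector(params)
  rows <- lapply(names(config$strategies), function(nm) {
    arm <- assemble_strategy(params, config$strategies[[nm]])
    tr <- run_cohort_trace(arm$M, init_vec, config$run$n_cycles,
                           cohort_size = 1)
    acc <- accrue_discounted_outcomes(
      tr, u, state_costs = arm$per_cycle, entry_costs = arm$entry,
      discount = params$discount, half_cycle = config$run$half_cycle,
      M = arm$M
    )
    data.frame(label = nm, cost = acc$cost, qalys = acc$qalys,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit the model from a configuration
#'
#' @param config A [dr_config()].
#' @param ... Passed on to [dr_cea()] (e.g. `keep_traces`).
#' @return A [dr_cea()] fit.
#' @export
dr_cea_from_config <- function(config, ...) {
  dr_cea(params = config$params, strategies = config$strategies,
         n_cycles = config$run$n_cycles,
         cohort_size = config$run$cohort_size,
         half_cycle = config$run$half_cycle, init = config$run$init,
         gdp = config$wtp$gdp, ...)
}

config_to_list <- function(config) {
  strip <- function(x) {
    x <- unclass(x)
    if (is.list(x)) lapply(x, strip)
    else if (!is.null(names(x))) as.list(x)
    else if (length(x) > 1) as.list(x)
    else x
  }
  strip(config)
}

#' Write a configuration to YAML
#'
#' @param config A [dr_config()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config_to_list(config), path, precision = 15L)
  invisible(path)
}

#' Read and validate a configuration file
#'
#' Loads a YAML configuration, overlays it on the package defaults
#' (missing keys keep their default values; an empty file yields the
#' full base-case configuration), rejects unknown keys with their path,
#' and re-validates every component invariant through the constructors,
#' reporting the offending field on violation.
#'
#' @param path YAML file path.
#' @return A [dr_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  loaded <- yaml::read_yaml(path)
  config <- dr_config()
  if (is.null(loaded)) return(config)

  merge_into <- function(default, new, where) {
    if (!is.list(new) || !is.list(default)) return(new)
    for (key in names(new)) {
      if (!key %in% names(default)) {
        stop("unknown configuration key: ",
             paste(c(where, key), collapse = "/"), call. = FALSE)
      }
      default[[key]] <- merge_into(default[[key]], new[[key]],
                                   c(where, key))
    }
    default
  }
  plain <- merge_into(config_to_list(config), loaded, character())

  params <- do.call(dr_parameters,
                    lapply(plain$params, function(x)
                      if (is.list(x)) unlist(x) else x))
  strategies <- lapply(plain$strategies, function(s) {
    s$treated_states <- unlist(s$treated_states)
    do.call(dr_strategy, s)
  })
  dr_config(params = params, strategies = strategies,
            n_cycles = plain$run$n_cycles,
            cohort_size = plain$run$cohort_size,
            half_cycle = plain$run$half_cycle, init = plain$run$init,
            gdp = plain$wtp$gdp,
            wtp_multipliers = unlist(plain$wtp$multipliers),
            seed = plain$run$seed)
}

#' Run a named analysis and export its artifacts
#'
#' Single entry point tying the pipeline together, mirroring the
#' command set of the shipped command-line wrapper: each command runs
#' the relevant part of the analysis from `config` and writes CSV/JSON
#' artifacts plus a run log (seed, package version, parameter digest)
#' into `out_dir`.
#'
#' Commands: `"trace"` (natural-history cohort trace), `"costs"`
#' (programme cost report), `"evaluate"` (incremental
#' cost-effectiveness table), `"tornado"`, `"psa"`, `"ceac"`,
#' `"simulate-screening"` (synthetic paired grading cohort),
#' `"agreement"` (agreement statistics on a synthetic cohort).
#'
#' @param command One of the commands above.
#' @param config A [dr_config()].
#' @param out_dir Output directory (created if missing).
#' @param seed Seed for stochastic commands; defaults to the
#'   configuration's seed.
#' @param n_draws PSA draws for `"psa"`/`"ceac"`.
#' @param wtp_grid WTP grid for `"ceac"`.
#' @param cohort_spec A [screening_cohort_spec()] for the screening
#'   commands.
#' @return Character vector of files written, invisibly.
#' @export
run_analysis <- function(command = c("trace", "costs", "evaluate",
                                     "tornado", "psa", "ceac",
                                     "simulate-screening", "agreement"),
                         config = dr_config(), out_dir = ".",
                         seed = NULL, n_draws = 10000,
                         wtp_grid = NULL,
                         cohort_spec = screening_cohort_spec()) {
  command <- match.arg(command)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (is.null(seed)) seed <- config$run$seed
  if (is.null(wtp_grid)) {
    wtp_grid <- seq(0, 1.2 * max(wtp_thresholds(config$wtp$gdp,
                                                config$wtp$multipliers)),
                    length.out = 25)
  }
  out <- function(name) file.path(out_dir, name)
  written <- character()
  emit <- function(df, name) {
    utils::write.csv(df, out(name), row.names = FALSE)
    written <<- c(written, out(name))
  }

  if (command == "trace") {
    fit <- dr_cea_from_config(config, keep_traces = TRUE)
    for (nm in names(fit$traces)) {
      emit(trace_as_data_frame(fit$traces[[nm]]),
           sprintf("trace_%s.csv", nm))
    }
  } else if (command == "costs") {
    rep_ <- rbind(
      cbind(strategy = "ai", cost_report(screening_cost_ledger("ai"))),
      cbind(strategy = "ophthalmologist",
            cost_report(screening_cost_ledger("ophthalmologist"))))
    emit(rep_, "costs.csv")
  } else if (command == "evaluate") {
    fit <- dr_cea_from_config(config)
    emit(as.data.frame(summary(fit)), "evaluation.csv")
  } else if (command == "tornado") {
    emit(as.data.frame(one_way_tornado(config)), "tornado.csv")
  } else if (command %in% c("psa", "ceac")) {
    psa <- run_psa(config, n_draws = n_draws, seed = seed)
    emit(as.data.frame(psa), "psa_samples.csv")
    if (command == "ceac") {
      emit(as.data.frame(ceac(psa, wtp_grid)), "ceac.csv")
    }
  } else if (command == "simulate-screening") {
    emit(simulate_screening_cohort(cohort_spec, seed = seed),
         "screening_cohort.csv")
  } else if (command == "agreement") {
    records <- simulate_screening_cohort(cohort_spec, seed = seed)
    tab <- agreement_table(records)
    stats <- agreement_statistics(tab)
    jsonlite::write_json(
      list(table = unclass(tab), statistics = stats),
      out("agreement.json"), auto_unbox = TRUE, digits = NA)
    written <- c(written, out("agreement.json"))
  }

  log_file <- out(sprintf("%s_run.log", command))
  leaves <- suppressWarnings(as.numeric(unlist(config_to_list(config))))
  digest <- sum(leaves[is.finite(leaves)])
  writeLines(c(
    sprintf("command: %s", command),
    sprintf("retscreen version: %s",
            as.character(utils::packageVersion("retscreen"))),
    sprintf("seed: %d", seed),
    sprintf("parameter digest: %.10g", digest),
    sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  ), log_file)
  written <- c(written, log_file)
  invisible(written)
}
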