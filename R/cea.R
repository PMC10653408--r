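#' Evaluate the DR screening cost-effectiveness model
#'
#' The package's central function: builds each strategy arm's transition
#' matrix and cost schedule, runs the discounted half-cycle-corrected
#' cohort simulation over the model horizon, and compares the arms by
#' incremental cost-effectiveness with dominance labelling.
#'
#' The base case follows the source study: a closed cohort of 10,000
#' rural diabetic patients, 50 annual cycles, all patients initially
#' alive without DR, 3% discounting of both costs and QALYs, and a
#' half-cycle correction treating transitions as mid-cycle events.
#'
#' @param params Natural-history parameters, see [dr_parameters()].
#' @param strategies Named list of [dr_strategy()] arms; defaults to the
#'   study's three comparators.
#' @param n_cycles Model horizon in years.
#' @param cohort_size Cohort head count (affects traces, not per-capita
#'   results).
#' @param half_cycle Apply the half-cycle correction.
#' @param init `"ndr"` or `"prevalence"` start, see
#'   [initial_distribution()].
#' @param gdp Per-capita GDP for the willingness-to-pay thresholds.
#' @param keep_traces Retain the full cohort traces in the result.
#' @return A `dr_cea` object: list with `outcomes` (per-capita discounted
#'   cost in RMB and QALYs per strategy), `frontier` (a [ce_frontier()]),
#'   `wtp` (thresholds), the arms and run settings. Methods: `print`,
#'   `summary`, `plot`, `simulate` (probabilistic sensitivity analysis).
#' @examples
#' fit <- dr_cea(n_cycles = 50)
#' fit
#' @export
dr_cea <- function(params = dr_parameters(),
                   strategies = default_strategies(),
                   n_cycles = 50L,
                   cohort_size = 10000,
                   half_cycle = TRUE,
                   init = c("ndr", "prevalence"),
                   gdp = 72447,
                   keep_traces = FALSE) {
  init <- match.arg(init)
  if (is.null(names(strategies))) {
    names(strategies) <- vapply(strategies, `[[`, "", "kind")
  }
  init_vec <- initial_distribution(params, init)
  u <- utility_vector(params)

  arms <- lapply(strategies, assemble_strategy, params = params)
  rows <- list()
  traces <- list()
  for (nm in names(arms)) {
    arm <- arms[[nm]]
    tr <- run_cohort_trace(arm$M, init_vec, n_cycles, cohort_size)
    acc <- accrue_discounted_outcomes(
      tr, u, state_costs = arm$per_cycle, entry_costs = arm$entry,
      discount = params$discount, half_cycle = half_cycle, M = arm$M
    )
    rows[[nm]] <- data.frame(label = nm, cost = acc$cost,
                             qalys = acc$qalys, stringsAsFactors = FALSE)
    if (keep_traces) traces[[nm]] <- tr
  }
  outcomes <- do.call(rbind, rows)
  rownames(outcomes) <- NULL

  structure(
    list(outcomes = outcomes,
         frontier = ce_frontier(outcomes),
         wtp = wtp_thresholds(gdp),
         params = params, strategies = strategies, arms = arms,
         traces = if (keep_traces) traces else NULL,
         settings = list(n_cycles = n_cycles, cohort_size = cohort_size,
                         half_cycle = half_cycle, init = init, gdp = gdp)),
    class = "dr_cea"
  )
}

#' @export
print.dr_cea <- function(x, ...) {
  cat(sprintf(
    "DR screening cost-effectiveness model (%d strategies, %d cycles, %s start)\n",
    nrow(x$outcomes), x$settings$n_cycles, x$settings$init))
  f <- x$frontier
  for (i in seq_len(nrow(f))) {
    cat(sprintf("  %-16s C = %9.2f RMB  E = %7.4f QALYs  %s%s\n",
                f$label[i], f$cost[i], f$qalys[i], f$dominance[i],
                ifelse(is.na(f$icer[i]), "",
                       sprintf(" (ICER %.0f RMB/QALY)", f$icer[i]))))
  }
  opt <- optimal_at_wtp(f, x$wtp[["3xGDP"]])
  cat(sprintf("  optimal at 3x GDP (%.0f RMB/QALY): %s\n",
              x$wtp[["3xGDP"]], opt))
  invisible(x)
}

#' Summarize a fitted cost-effectiveness model
#'
#' Produces the incremental comparison table of the study's results
#' (effectiveness, incremental effectiveness, cost in RMB and USD,
#' incremental cost, ICER, dominance), ordered by ascending cost, each
#' strategy compared with its predecessor in that order.
#'
#' @param object A [dr_cea()] fit.
#' @param ... Unused.
#' @return A `summary.dr_cea` data frame.
#' @export
summary.dr_cea <- function(object, ...) {
  f <- object$frontier
  n <- nrow(f)
  inc_e <- c(NA, diff(f$qalys))
  inc_c <- c(NA, diff(f$cost))
  pairwise <- c(NA_real_, ifelse(diff(f$qalys) != 0,
                                 diff(f$cost) / diff(f$qalys), NA_real_))
  out <- data.frame(
    strategy = f$label,
    qalys = f$qalys,
    inc_qalys = inc_e,
    cost_rmb = f$cost,
    cost_usd = convert_currency(f$cost, "RMB"),
    inc_cost_rmb = inc_c,
    icer_rmb_per_qaly = pairwise,
    dominance = f$dominance,
    stringsAsFactors = FALSE
  )
  structure(out, class = c("summary.dr_cea", "data.frame"),
            wtp = object$wtp)
}

#' @export
print.summary.dr_cea <- function(x, ...) {
  cat("Cost-effectiveness of DR screening strategies (per capita, discounted)\n\n")
  print.data.frame(x, row.names = FALSE, digits = 6)
  wtp <- attr(x, "wtp")
  cat(sprintf("\nWTP thresholds: %s RMB/QALY\n",
              paste(sprintf("%s = %.0f", names(wtp), wtp), collapse = ", ")))
  invisible(x)
}

#' Plot the cost-effectiveness plane
#'
#' Strategies on the cost-effectiveness plane (QALYs vs cost), with the
#' frontier drawn as the cost-effect boundary line and dominated
#' strategies marked.
#'
#' @param x A [dr_cea()] fit.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.dr_cea <- function(x, ...) {
  f <- x$frontier
  graphics::plot(f$qalys, f$cost, pch = 19,
                 xlab = "Effectiveness (QALYs)", ylab = "Cost (RMB)",
                 main = "Cost-effectiveness plane", ...)
  on_f <- f[f$dominance == "on frontier", ]
  graphics::lines(on_f$qalys, on_f$cost, col = "steelblue", lwd = 2)
  graphics::text(f$qalys, f$cost, f$label, pos = 3, cex = 0.8)
  dom <- f$dominance != "on frontier"
  if (any(dom)) {
    graphics::points(f$qalys[dom], f$cost[dom], pch = 4, cex = 1.6,
                     col = "firebrick")
  }
  invisible(x)
}
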