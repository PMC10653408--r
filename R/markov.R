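#' Build the per-cycle transition matrix
#'
#' Constructs the 7x7 annual transition matrix of the DR model from the
#' natural-history parameters. Death is resolved first each cycle, then
#' the survivors either progress one stage or stay: for an alive state
#' with annual progression probability `p` and composed death probability
#' `d`, `P(die) = d`, `P(progress) = (1 - d) * p * modifier` and
#' `P(stay)` the remainder. Blindness only stays or dies; death is
#' absorbing. This death-first composition keeps each row stochastic
#' without renormalization.
#'
#' @param params A [dr_parameters()] object.
#' @param modifier Numeric vector of 5 multipliers in `[0, 1]` applied to
#'   the progression probabilities of the five progressing states
#'   (NDR ... PDR); screening arms use it to encode the treatment effect.
#' @return A 7x7 row-stochastic matrix with state dimnames.
#' @examples
#' M <- build_transition_matrix(dr_parameters())
#' rowSums(M)
#' @export
build_transition_matrix <- function(params, modifier = rep(1, 5)) {
  check_probability(modifier, "modifier")
  stopifnot(length(modifier) == 5L)
  d <- death_probabilities(params)
  M <- matrix(0, N_STATES, N_STATES,
              dimnames = list(health_states(), health_states()))
  for (s in NONBLIND_ALIVE) {
    p <- params$progression[[s]] * modifier[[s]]
    probs <- c(stay = (1 - d[[s]]) * (1 - p),
               progress = (1 - d[[s]]) * p,
               die = d[[s]])
    if (any(probs < 0) || any(probs > 1)) {
      stop("composed transition probabilities outside [0, 1] for state ",
           health_states()[s])
    }
    M[s, s] <- probs[["stay"]]
    M[s, s + 1L] <- probs[["progress"]]
    M[s, DEAD] <- probs[["die"]]
  }
  M[BLIND, BLIND] <- 1 - d[[BLIND]]
  M[BLIND, DEAD] <- d[[BLIND]]
  M[DEAD, DEAD] <- 1
  M
}

#' Validate a transition matrix
#'
#' Checks the structural invariants the cohort engine relies on:
#' nonnegative entries, unit row sums, an absorbing death state, and no
#' transitions other than stay / one-step progression / death.
#'
#' @param M A 7x7 matrix.
#' @param tol Tolerance on row sums.
#' @return `M`, invisibly; errors otherwise.
#' @export
validate_transition_matrix <- function(M, tol = 1e-9) {
  stopifnot(is.matrix(M), dim(M) == c(N_STATES, N_STATES))
  if (any(M < 0)) stop("transition matrix has negative entries")
  if (any(abs(rowSums(M) - 1) > tol)) {
    stop("transition matrix rows must sum to 1")
  }
  if (!isTRUE(all.equal(unname(M[DEAD, ]), c(rep(0, 6), 1),
                        tolerance = tol))) {
    stop("death must be absorbing")
  }
  allowed <- diag(N_STATES) > 0
  for (s in NONBLIND_ALIVE) allowed[s, s + 1L] <- TRUE
  allowed[, DEAD] <- TRUE
  if (any(M[!allowed] != 0)) {
    stop("transition matrix has entries outside the permitted paths")
  }
  invisible(M)
}

#' Run a Markov cohort trace
#'
#' Propagates an initial distribution through the transition matrix for
#' `n_cycles` annual cycles, tracking state occupancy of a closed cohort.
#'
#' @param M Transition matrix (rows must sum to 1).
#' @param init Probability vector over the 7 states (sums to 1).
#' @param n_cycles Number of cycles (>= 1); the study runs 50.
#' @param cohort_size Cohort head count the occupancies are scaled to.
#' @return A `cohort_trace`: an `(n_cycles + 1) x 7` occupancy matrix,
#'   row 1 being the initial distribution, with attribute `cohort_size`.
#' @examples
#' tr <- run_cohort_trace(build_transition_matrix(dr_parameters()),
#'                        initial_distribution(dr_parameters()),
#'                        n_cycles = 5)
#' rowSums(tr)
#' @export
run_cohort_trace <- function(M, init, n_cycles = 50L, cohort_size = 1) {
  if (any(abs(rowSums(M) - 1) > 1e-9) || any(M < 0)) {
    stop("non-stochastic transition matrix")
  }
  check_probability(init, "init")
  stopifnot(length(init) == N_STATES, n_cycles >= 1)
  if (abs(sum(init) - 1) > 1e-9) stop("'init' must sum to 1")
  trace <- matrix(0, n_cycles + 1L, N_STATES,
                  dimnames = list(cycle = 0:n_cycles, health_states()))
  trace[1L, ] <- init * cohort_size
  for (t in seq_len(n_cycles)) {
    trace[t + 1L, ] <- trace[t, ] %*% M
  }
  structure(trace, cohort_size = cohort_size, class = c("cohort_trace", "matrix"))
}

#' Per-cycle inflow of new entrants into a state
#'
#' Counts, for each cycle, the cohort members arriving in `state` from a
#' different state: `inflow(t, s) = sum_{s' != s} occ(t-1, s') M[s', s]`,
#' reported at the arrival node `t = 1 ... n_cycles`. Used to attach
#' one-time costs (e.g. laser treatment on entry into a treated state);
#' with `state = "dead"` it yields deaths per cycle.
#'
#' @param trace A `cohort_trace` produced by `M`.
#' @param M The transition matrix that generated `trace`.
#' @param state State label or index; `NULL` returns the full
#'   `n_cycles x 7` inflow matrix.
#' @return Numeric vector of inflows per cycle (or a matrix).
#' @export
new_entrants <- function(trace, M, state = NULL) {
  n <- nrow(trace) - 1L
  inflow <- matrix(0, n, N_STATES, dimnames = list(cycle = 1:n, health_states()))
  for (t in seq_len(n)) {
    inflow[t, ] <- trace[t, ] %*% M - trace[t, ] * diag(M)
  }
  if (is.null(state)) return(inflow)
  if (is.character(state)) state <- state_index(state)
  inflow[, state]
}

#' Accrue discounted costs and QALYs over a cohort trace
#'
#' Sums per-capita discounted rewards over the run. Rewards are evaluated
#' at the cycle nodes `t = 0 ... n`: node `t` contributes
#' `occupancy(t) * reward * (1 + r)^-t`. With half-cycle correction on
#' (the default, mirroring the study's semiperiodic correction) the two
#' boundary nodes get weight 1/2 and interior nodes weight 1 — the
#' trapezoid rule, equivalent to treating transitions as mid-cycle events.
#' With it off, rewards accrue at end of cycle (nodes `1 ... n` with full
#' weight), so a single alive state with survival `s` yields the geometric
#' sum `u * sum_t s^t (1+r)^-t`.
#'
#' One-time entry costs are charged to [new_entrants()] of each state at
#' their arrival node (and, if `charge_initial`, to the cycle-0 occupants
#' of states with a nonzero entry cost, undiscounted).
#'
#' @param trace A `cohort_trace`.
#' @param utilities Numeric vector of 7 per-state QALY weights per year.
#' @param state_costs Numeric vector of 7 per-state per-cycle costs.
#' @param entry_costs Numeric vector of 7 one-time costs on entry.
#' @param discount Annual discount rate (shared by costs and effects).
#' @param half_cycle Logical; apply the half-cycle correction.
#' @param M Transition matrix; required when any `entry_costs` are nonzero.
#' @param charge_initial Charge entry costs to initial occupants as well.
#' @return List with per-capita `cost` and `qalys`.
#' @export
accrue_discounted_outcomes <- function(trace, utilities,
                                       state_costs = numeric(N_STATES),
                                       entry_costs = numeric(N_STATES),
                                       discount = 0.03,
                                       half_cycle = TRUE,
                                       M = NULL,
                                       charge_initial = TRUE) {
  stopifnot(length(utilities) == N_STATES,
            length(state_costs) == N_STATES,
            length(entry_costs) == N_STATES)
  if (any(utilities < 0) || any(state_costs < 0) || any(entry_costs < 0)) {
    stop("negative utilities or costs are not allowed")
  }
  n <- nrow(trace) - 1L
  size <- attr(trace, "cohort_size")
  if (is.null(size)) size <- 1
  disc <- (1 + discount)^-(0:n)
  w <- if (half_cycle) c(0.5, rep(1, n - 1L), 0.5) else c(0, rep(1, n))

  qalys <- sum(as.vector(trace %*% utilities) * w * disc)
  cost <- sum(as.vector(trace %*% state_costs) * w * disc)

  if (any(entry_costs > 0)) {
    if (is.null(M)) stop("'M' is required to attribute one-time entry costs")
    inflow <- new_entrants(trace, M)
    cost <- cost + sum(as.vector(inflow %*% entry_costs) * disc[-1L])
    if (charge_initial) cost <- cost + sum(trace[1L, ] * entry_costs)
  }
  list(cost = cost / size, qalys = qalys / size)
}

#' Export a cohort trace as a long data frame
#'
#' @param trace A `cohort_trace`.
#' @return Data frame with columns `cycle`, `state`, `occupancy`
#'   (one row per cycle and state), suitable for CSV export.
#' @export
trace_as_data_frame <- function(trace) {
  n <- nrow(trace) - 1L
  data.frame(
    cycle = rep(0:n, times = N_STATES),
    state = rep(health_states(), each = n + 1L),
    occupancy = as.vector(trace[, seq_len(N_STATES)]),
    stringsAsFactors = FALSE
  )
}
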