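#' Natural-history and valuation parameters of the DR model
#'
#' Bundles every disease-level input of the Markov model: annual stage
#' progression probabilities, the initial DR stage distribution among
#' diabetic patients, background mortality with diabetes and blindness
#' multipliers, state utility weights and the annual discount rate.
#' Defaults are the base-case values of the rural Chinese screening study
#' the package models.
#'
#' Mortality is composed per state from the natural annual death
#' probability of the rural population (`p_die`, stored as a probability;
#' 7.07 per mille) and two multipliers. Under the default wiring
#' (`mortality_wiring = "diabetes"`) every alive non-blind state dies at
#' `p_die * mult_diabetes` and the blind state at
#' `p_die * mult_diabetes * mult_blindness`. The alternative wiring
#' (`"blindness"`) applies `p_die * mult_blindness` to non-blind states
#' instead (and additionally `mult_diabetes` to the blind state); it
#' reproduces the study's printed 5-cycle death fraction (6.5%) whereas the
#' default reproduces its 50-cycle state distribution, the two being
#' mutually inconsistent in the source.
#'
#' @param progression Named numeric vector of 5 annual one-step progression
#'   probabilities (`no_to_mild`, `mild_to_moderate`, `moderate_to_severe`,
#'   `severe_to_PDR`, `PDR_to_blindness`).
#' @param prevalence Named numeric vector of 5 probabilities over the alive
#'   non-blind states; must sum to 1 (used when the cohort starts at the
#'   observed stage distribution rather than all-NDR).
#' @param p_die Annual natural mortality probability.
#' @param mult_diabetes,mult_blindness Mortality multipliers (>= 1).
#' @param mortality_wiring `"diabetes"` (default) or `"blindness"`; see
#'   Details.
#' @param utilities Named numeric vector of QALY weights for `NDR`, `NPDR`
#'   (shared by the three NPDR grades), `PDR` and `blindness`. Death is
#'   fixed at 0. Weights above 1 are tolerated up to 1.2 because published
#'   uncertainty ranges exceed 1.
#' @param discount Annual discount rate applied to both costs and effects,
#'   in `[0, 0.06]`.
#'
#' @return An object of class `dr_params`.
#' @examples
#' p <- dr_parameters()
#' p$progression[["no_to_mild"]]
#' @seealso [build_transition_matrix()], [dr_cea()]
#' @export
dr_parameters <- function(progression = c(no_to_mild = 0.07,
                                          mild_to_moderate = 0.19,
                                          moderate_to_severe = 0.17,
                                          severe_to_PDR = 0.29,
                                          PDR_to_blindness = 0.21),
                          prevalence = c(NDR = 0.6254,
                                         mild_NPDR = 0.0812,
                                         moderate_NPDR = 0.1449,
                                         severe_NPDR = 0.1022,
                                         PDR = 0.0463),
                          p_die = 0.00707,
                          mult_diabetes = 2.34,
                          mult_blindness = 1.9,
                          mortality_wiring = c("diabetes", "blindness"),
                          utilities = c(NDR = 0.94, NPDR = 0.87,
                                        PDR = 0.83, blindness = 0.81),
                          discount = 0.03) {
  mortality_wiring <- match.arg(mortality_wiring)
  progression <- unlist(progression)
  prevalence <- unlist(prevalence)
  utilities <- unlist(utilities)

  check_probability(progression, "progression")
  stopifnot(length(progression) == 5L)
  check_probability(prevalence, "prevalence")
  stopifnot(length(prevalence) == 5L)
  if (abs(sum(prevalence) - 1) > 1e-9) {
    stop("'prevalence' must sum to 1 (got ", format(sum(prevalence)), ")")
  }
  check_probability(p_die, "p_die")
  if (mult_diabetes < 1 || mult_blindness < 1) {
    stop("mortality multipliers must be >= 1")
  }
  check_probability(utilities, "utilities", max = 1.2)
  stopifnot(length(utilities) == 4L)
  check_probability(discount, "discount", max = 0.06)

  structure(
    list(progression = progression, prevalence = prevalence,
         p_die = p_die, mult_diabetes = mult_diabetes,
         mult_blindness = mult_blindness,
         mortality_wiring = mortality_wiring,
         utilities = utilities, discount = discount),
    class = "dr_params"
  )
}

#' Per-state annual death probabilities
#'
#' Composes background mortality with the diabetes and blindness
#' multipliers according to the wiring chosen in [dr_parameters()].
#'
#' @param params A `dr_params` object.
#' @return Numeric vector of 6 death probabilities for the alive states
#'   (NDR ... blindness).
#' @export
death_probabilities <- function(params) {
  base <- switch(params$mortality_wiring,
                 diabetes = params$p_die * params$mult_diabetes,
                 blindness = params$p_die * params$mult_blindness)
  extra <- switch(params$mortality_wiring,
                  diabetes = params$mult_blindness,
                  blindness = params$mult_diabetes)
  d <- c(rep(base, 5), base * extra)
  if (any(d > 1)) stop("composed death probability exceeds 1")
  names(d) <- health_states()[ALIVE_STATES]
  d
}

#' Expand the four utility weights to the seven model states
#'
#' @param params A `dr_params` object.
#' @return Numeric vector of length 7 (death = 0), named by state.
#' @export
utility_vector <- function(params) {
  u <- params$utilities
  v <- c(u[["NDR"]], u[["NPDR"]], u[["NPDR"]], u[["NPDR"]],
         u[["PDR"]], u[["blindness"]], 0)
  names(v) <- health_states()
  v
}

#' Initial cohort distribution
#'
#' @param params A `dr_params` object.
#' @param mode `"ndr"` starts the whole cohort alive without DR (the
#'   study's stated initial stage, used for both the natural-history queue
#'   analysis and the base-case cost-effectiveness comparison);
#'   `"prevalence"` starts at the observed DR stage distribution.
#' @return Probability vector of length 7 over the model states.
#' @export
initial_distribution <- function(params, mode = c("ndr", "prevalence")) {
  mode <- match.arg(mode)
  init <- numeric(N_STATES)
  names(init) <- health_states()
  if (mode == "ndr") {
    init[1L] <- 1
  } else {
    init[NONBLIND_ALIVE] <- params$prevalence
  }
  init
}

#' @export
print.dr_params <- function(x, ...) {
  cat("DR natural-history parameters\n")
  cat("  progression: ",
      paste(sprintf("%s=%.3g", names(x$progression), x$progression),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  p_die=%.5f (x%.2f diabetes, x%.2f blindness; wiring '%s')\n",
              x$p_die, x$mult_diabetes, x$mult_blindness, x$mortality_wiring))
  cat("  utilities: ",
      paste(sprintf("%s=%.2f", names(x$utilities), x$utilities),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  discount rate: %.1f%%\n", 100 * x$discount))
  invisible(x)
}
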