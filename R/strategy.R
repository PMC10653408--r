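#' Treatment-blended progression probability
#'
#' Mixes treated and untreated progression for a screened state: a
#' fraction `sens` of patients is detected and progresses at the reduced
#' rate `rr * p` (laser photocoagulation), while the missed fraction
#' `1 - sens` progresses at the natural rate `p`:
#' `sens * rr * p + (1 - sens) * p`.
#'
#' @param p Annual progression probability out of the state.
#' @param sens Probability that a patient in the state is detected and
#'   treated in a cycle.
#' @param rr Relative risk of progression under laser treatment, in
#'   `(0, 1]`.
#' @return The effective annual progression probability.
#' @examples
#' blended_progression(0.29, sens = 1, rr = 0.49) # 0.1421
#' @export
blended_progression <- function(p, sens, rr) {
  check_probability(p, "p")
  check_probability(sens, "sens")
  if (any(rr <= 0) || any(rr > 1)) stop("'rr' must be in (0, 1]")
  sens * rr * p + (1 - sens) * p
}

#' Define a screening strategy arm
#'
#' A strategy bundles the screening test's operating characteristics, the
#' programme's observed positive detection rate, the laser-treatment
#' effect and the per-state cost schedule. The `"none"` arm disables all
#' screening effects and costs.
#'
#' Two quantities govern the screened arms. The *published* test
#' sensitivity/specificity drive referral costs: patients in a treated
#' (referable) state incur the diagnostic work-up weighted by
#' `sensitivity`, and patients in the non-referable alive states incur a
#' false-positive work-up weighted by `1 - specificity` (toggle
#' `false_positive_referral`). The annual probability that a diseased
#' patient is actually detected and treated — which scales both the
#' progression reduction and the one-time laser cost — is set by
#' `uptake`: `"detection"` (default) uses the programme's observed
#' positive detection rate, `"sensitivity"` uses the published test
#' sensitivity. The detection-rate default is what reproduces the
#' source study's effectiveness ordering of the arms; see the methods
#' vignette.
#'
#' @param kind `"none"`, `"ai"` or `"ophthalmologist"`.
#' @param sensitivity,specificity Published test performance for
#'   referable DR, in `[0, 1]`.
#' @param detection Observed positive detection rate of the programme.
#' @param rr_laser Relative risk of progression under laser treatment.
#' @param uptake Which rate keys annual treatment uptake (see Details).
#' @param screening_cost Per-capita annual programme screening cost (RMB).
#' @param screening_transport Per-capita transport to the screening site.
#' @param followup_cost Referral diagnostic work-up cost per visit.
#' @param hospital_transport Round-trip transport to the referral
#'   hospital.
#' @param laser_cost One-time laser photocoagulation cost.
#' @param vitrectomy_cost One-time vitrectomy cost (PDR only).
#' @param include_vitrectomy Add vitrectomy to the PDR entry cost
#'   (disabled by default; the study's treatment assumption mentions
#'   laser only).
#' @param false_positive_referral Charge false-positive work-ups in the
#'   NDR-to-moderate states.
#' @param treatment_timing `"entry"` charges treatment once on entry into
#'   a treated state (laser is an episode, not an annuity);
#'   `"per_cycle"` charges it every cycle instead.
#' @param treated_states States whose patients receive treatment when
#'   detected.
#' @return A `dr_strategy` object.
#' @seealso [default_strategies()], [assemble_strategy()]
#' @export
dr_strategy <- function(kind = c("none", "ai", "ophthalmologist"),
                        sensitivity = 0, specificity = 1, detection = 0,
                        rr_laser = 0.49,
                        uptake = c("detection", "sensitivity"),
                        screening_cost = 0,
                        screening_transport = 0,
                        followup_cost = 0,
                        hospital_transport = 0,
                        laser_cost = 0,
                        vitrectomy_cost = 0,
                        include_vitrectomy = FALSE,
                        false_positive_referral = TRUE,
                        treatment_timing = c("entry", "per_cycle"),
                        treated_states = c("severe_NPDR", "PDR")) {
  kind <- match.arg(kind)
  uptake <- match.arg(uptake)
  treatment_timing <- match.arg(treatment_timing)
  check_probability(c(sensitivity, specificity, detection),
                    "sensitivity/specificity/detection")
  if (rr_laser <= 0 || rr_laser > 1) stop("'rr_laser' must be in (0, 1]")
  costs <- c(screening_cost, screening_transport, followup_cost,
             hospital_transport, laser_cost, vitrectomy_cost)
  if (any(costs < 0)) stop("costs must be nonnegative")
  if (kind == "none") {
    sensitivity <- 0; specificity <- 1; detection <- 0
    screening_cost <- screening_transport <- followup_cost <- 0
    hospital_transport <- laser_cost <- vitrectomy_cost <- 0
  }
  structure(
    list(kind = kind, sensitivity = sensitivity, specificity = specificity,
         detection = detection, rr_laser = rr_laser, uptake = uptake,
         screening_cost = screening_cost,
         screening_transport = screening_transport,
         followup_cost = followup_cost,
         hospital_transport = hospital_transport,
         laser_cost = laser_cost, vitrectomy_cost = vitrectomy_cost,
         include_vitrectomy = include_vitrectomy,
         false_positive_referral = false_positive_referral,
         treatment_timing = treatment_timing,
         treated_states = treated_states),
    class = "dr_strategy"
  )
}

#' The study's three comparator arms
#'
#' No screening; annual AI-based screening (published sensitivity 90.79%,
#' specificity 98.50%, observed detection rate 32.59%); annual
#' ophthalmologist screening (sensitivity 96%, specificity 94.67%,
#' detection rate 16.54%). Screening costs come from the shipped
#' programme ledgers ([screening_cost_ledger()]), patient-level unit
#' costs from [patient_unit_costs()].
#'
#' @param uptake Treatment-uptake convention passed to every screened
#'   arm; see [dr_strategy()].
#' @return Named list of three `dr_strategy` objects
#'   (`none`, `ai`, `ophthalmologist`).
#' @export
default_strategies <- function(uptake = c("detection", "sensitivity")) {
  uptake <- match.arg(uptake)
  unit <- patient_unit_costs()
  shared <- list(
    rr_laser = 0.49, uptake = uptake,
    screening_transport = unit[["screening_transport"]],
    followup_cost = unit[["followup"]],
    hospital_transport = unit[["hospital_transport"]],
    laser_cost = unit[["laser"]],
    vitrectomy_cost = unit[["vitrectomy"]]
  )
  ai <- do.call(dr_strategy, c(list(
    kind = "ai", sensitivity = 0.9079, specificity = 0.985,
    detection = 0.3259,
    screening_cost = per_capita_screening_cost(screening_cost_ledger("ai"))
  ), shared))
  oph <- do.call(dr_strategy, c(list(
    kind = "ophthalmologist", sensitivity = 0.96, specificity = 0.9467,
    detection = 0.1654,
    screening_cost = per_capita_screening_cost(
      screening_cost_ledger("ophthalmologist"))
  ), shared))
  list(none = dr_strategy("none"), ai = ai, ophthalmologist = oph)
}

uptake_rate <- function(strategy) {
  switch(strategy$uptake,
         detection = strategy$detection,
         sensitivity = strategy$sensitivity)
}

#' Per-state cost schedule of a strategy
#'
#' Translates a strategy definition into the two cost vectors the cohort
#' engine consumes. For screened arms every alive state accrues the
#' per-capita screening cost plus screening transport each cycle; the
#' treated (referable) states additionally accrue the
#' sensitivity-weighted referral work-up plus hospital transport; the
#' non-referable alive states (NDR to moderate NPDR) accrue a
#' false-positive work-up weighted by `1 - specificity`. Treatment
#' (laser, optionally vitrectomy for PDR) is a one-time entry cost
#' weighted by the treatment-uptake rate, or a per-cycle cost under
#' `treatment_timing = "per_cycle"`. The `"none"` arm is all zeros.
#'
#' @param strategy A [dr_strategy()].
#' @return List with `per_cycle` and `entry` cost vectors (length 7, RMB).
#' @export
per_cycle_state_costs <- function(strategy) {
  per_cycle <- numeric(N_STATES)
  entry <- numeric(N_STATES)
  names(per_cycle) <- names(entry) <- health_states()
  if (strategy$kind == "none") {
    return(list(per_cycle = per_cycle, entry = entry))
  }
  treated <- state_index(strategy$treated_states)
  referral <- strategy$followup_cost + strategy$hospital_transport

  per_cycle[ALIVE_STATES] <- strategy$screening_cost +
    strategy$screening_transport
  per_cycle[treated] <- per_cycle[treated] + strategy$sensitivity * referral
  if (strategy$false_positive_referral) {
    fp <- setdiff(NONBLIND_ALIVE, treated)
    per_cycle[fp] <- per_cycle[fp] + (1 - strategy$specificity) * referral
  }

  w <- uptake_rate(strategy)
  treat_cost <- numeric(N_STATES)
  treat_cost[treated] <- w * strategy$laser_cost
  if (strategy$include_vitrectomy) {
    pdr <- state_index("PDR")
    treat_cost[pdr] <- treat_cost[pdr] + w * strategy$vitrectomy_cost
  }
  if (strategy$treatment_timing == "entry") {
    entry <- entry + treat_cost
  } else {
    per_cycle <- per_cycle + treat_cost
  }
  if (any(per_cycle < 0) || any(entry < 0)) stop("negative composed cost")
  list(per_cycle = per_cycle, entry = entry)
}

#' Assemble a strategy arm for the cohort engine
#'
#' Combines natural history with the strategy's treatment effect and cost
#' schedule. Progression out of the treated states is
#' [blended_progression()] at the arm's treatment-uptake rate; all other
#' transitions equal natural history.
#'
#' @param params A [dr_parameters()] object.
#' @param strategy A [dr_strategy()].
#' @return A `dr_arm`: list with the transition matrix `M`, cost vectors
#'   `per_cycle` and `entry`, and the strategy `label`.
#' @export
assemble_strategy <- function(params, strategy) {
  modifier <- rep(1, 5)
  if (strategy$kind != "none") {
    w <- uptake_rate(strategy)
    treated <- intersect(state_index(strategy$treated_states),
                         NONBLIND_ALIVE)
    for (s in treated) {
      p <- params$progression[[s]]
      modifier[s] <- if (p > 0) {
        blended_progression(p, w, strategy$rr_laser) / p
      } else 1
    }
  }
  M <- build_transition_matrix(params, modifier)
  validate_transition_matrix(M)
  costs <- per_cycle_state_costs(strategy)
  structure(list(M = M, per_cycle = costs$per_cycle, entry = costs$entry,
                 label = strategy$kind),
            class = "dr_arm")
}
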