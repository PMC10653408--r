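#' Specification of a synthetic paired-grading cohort
#'
#' Describes the statistical structure of the study's screening dataset
#' so that agreement statistics can be exercised without any patient
#' data: cohort size, the true DR grade distribution, and each grader's
#' sensitivity/specificity for the binary any-DR call. The default
#' emulates the field cohort: 3,102 patients, an any-DR prevalence of
#' 16.54% split over grades in proportion to the study's graded-eye
#' distribution, and the published performance of the AI system and the
#' ophthalmologist panel. This is a synthetic stand-in — see the methods
#' vignette for what it does and does not emulate.
#'
#' @param n Number of patients.
#' @param grade_prevalence Named probability vector over the five true
#'   grades (NDR ... PDR); must sum to 1.
#' @param graders Named list; each element is `c(sensitivity, specificity)`
#'   for the binary any-DR call.
#' @param ungradable_rate Probability that an eye is ungradable by a
#'   grader (patients whose both eyes are ungradable get an `NA` call and
#'   are excluded from agreement statistics).
#' @return A `screening_cohort_spec` object.
#' @export
screening_cohort_spec <- function(n = 3102,
                                  grade_prevalence = c(
                                    NDR = 0.8346,
                                    mild_NPDR = 0.0297,
                                    moderate_NPDR = 0.0479,
                                    severe_NPDR = 0.0784,
                                    PDR = 0.0094),
                                  graders = list(
                                    ai = c(sensitivity = 0.9079,
                                           specificity = 0.985),
                                    ophthalmologist = c(sensitivity = 0.96,
                                                        specificity = 0.9467)),
                                  ungradable_rate = 0) {
  if (n < 1) stop("cohort size must be at least 1")
  grade_prevalence <- unlist(grade_prevalence)
  stopifnot(length(grade_prevalence) == 5L)
  check_probability(grade_prevalence, "grade_prevalence")
  if (abs(sum(grade_prevalence) - 1) > 1e-9) {
    stop("'grade_prevalence' must sum to 1")
  }
  stopifnot(length(graders) >= 1, !is.null(names(graders)))
  for (g in graders) check_probability(g, "grader performance")
  check_probability(ungradable_rate, "ungradable_rate")
  structure(list(n = n, grade_prevalence = grade_prevalence,
                 graders = graders, ungradable_rate = ungradable_rate),
            class = "screening_cohort_spec")
}

#' Simulate a paired DR grading cohort
#'
#' Draws each patient's true grade from the prevalence vector, then each
#' grader's patient-level any-DR call conditionally on the true status:
#' a truly diseased patient is called positive with probability equal to
#' the grader's sensitivity, a healthy one with `1 - specificity`. So
#' each grader's expected positive-call rate is
#' `prev * sens + (1 - prev) * (1 - spec)`. Per-eye grades are then
#' emitted consistently with the worse-eye diagnosis rule (the patient
#' call equals the worse eye's grade): the worse eye of a detected case
#' carries the true grade (a false positive is graded mild NPDR), the
#' fellow eye is NDR, and a negative call grades both eyes NDR.
#' Grade-level confusion between DR grades is not modelled — the binary
#' referral call is what the agreement statistics consume.
#'
#' @param spec A [screening_cohort_spec()].
#' @param seed Seed making the cohort reproducible.
#' @return Data frame with one row per patient: `patient`, `true_grade`,
#'   and per grader `<g>_call` (logical, `NA` if ungradable) plus
#'   `<g>_eye1` / `<g>_eye2` grades.
#' @export
simulate_screening_cohort <- function(spec = screening_cohort_spec(),
                                      seed = 1) {
  grades <- health_states()[NONBLIND_ALIVE]
  with_seed(seed, {
    true_grade <- sample(grades, spec$n, replace = TRUE,
                         prob = spec$grade_prevalence)
    is_dr <- true_grade != "NDR"
    out <- data.frame(patient = seq_len(spec$n), true_grade = true_grade,
                      stringsAsFactors = FALSE)
    for (g in names(spec$graders)) {
      perf <- spec$graders[[g]]
      p_pos <- ifelse(is_dr, perf[["sensitivity"]],
                      1 - perf[["specificity"]])
      call <- stats::runif(spec$n) < p_pos
      if (spec$ungradable_rate > 0) {
        both_ungradable <- stats::runif(spec$n) < spec$ungradable_rate^2
        call[both_ungradable] <- NA
      }
      worse <- ifelse(is.na(call), NA_character_,
                      ifelse(!call, "NDR",
                             ifelse(is_dr, true_grade, "mild_NPDR")))
      out[[paste0(g, "_call")]] <- call
      out[[paste0(g, "_eye1")]] <- worse
      out[[paste0(g, "_eye2")]] <- ifelse(is.na(call), NA_character_, "NDR")
    }
    out
  })
}

#' Cross-classify two graders' patient-level calls
#'
#' @param records A [simulate_screening_cohort()] data frame (or any data
#'   frame with logical `<g>_call` columns).
#' @param graders Length-2 character vector naming the graders to
#'   compare. Patients with an `NA` call from either grader are excluded.
#' @return An `agreement_table`: list with `a` (both positive), `b`
#'   (first grader only), `c` (second only), `d` (both negative) and `n`.
#' @export
agreement_table <- function(records,
                            graders = c("ai", "ophthalmologist")) {
  stopifnot(length(graders) == 2)
  cols <- paste0(graders, "_call")
  if (!all(cols %in% names(records))) {
    stop("records lack call columns for graders: ",
         paste(graders, collapse = ", "))
  }
  g1 <- records[[cols[1]]]
  g2 <- records[[cols[2]]]
  keep <- !is.na(g1) & !is.na(g2)
  g1 <- g1[keep]; g2 <- g2[keep]
  structure(list(a = sum(g1 & g2), b = sum(g1 & !g2),
                 c = sum(!g1 & g2), d = sum(!g1 & !g2),
                 n = length(g1), graders = graders),
            class = "agreement_table")
}

#' Agreement and detection statistics for a 2x2 grading table
#'
#' Computes the statistics the study reports for its paired screening
#' results: the diagnostic coincidence rate `(a + d) / n`, Cohen's
#' chance-corrected kappa `(po - pe) / (1 - pe)` with the expected
#' agreement `pe` taken from the table margins, and each grader's
#' positive detection rate.
#'
#' @param table An [agreement_table()], or a list with counts `a`, `b`,
#'   `c`, `d`.
#' @return List with `coincidence`, `kappa` (`NA` with an explanatory
#'   `kappa_verdict` when the margins are degenerate, i.e. `pe = 1`),
#'   and `detection` (named per-grader positive rates).
#' @examples
#' agreement_statistics(list(a = 40, b = 5, c = 3, d = 52))
#' @export
agreement_statistics <- function(table) {
  a <- table$a; b <- table$b; cc <- table$c; d <- table$d
  n <- a + b + cc + d
  if (n <= 0) stop("empty table")
  po <- (a + d) / n
  pe <- ((a + b) * (a + cc) + (cc + d) * (b + d)) / n^2
  kappa <- if (abs(1 - pe) < 1e-12) NA_real_ else (po - pe) / (1 - pe)
  detection <- c((a + b) / n, (a + cc) / n)
  names(detection) <- table$graders %||% c("grader1", "grader2")
  list(coincidence = po, kappa = kappa,
       kappa_verdict = if (is.na(kappa)) "undefined: degenerate margins"
                       else "defined",
       detection = detection)
}

#' @export
print.agreement_table <- function(x, ...) {
  cat(sprintf("Paired grading table (%s vs %s), n = %d\n",
              x$graders[1], x$graders[2], x$n))
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, byrow = TRUE,
              dimnames = list(paste(x$graders[1], c("+", "-")),
                              paste(x$graders[2], c("+", "-"))))
  print(m)
  s <- agreement_statistics(x)
  cat(sprintf("coincidence %.4f, kappa %.4f\n", s$coincidence, s$kappa))
  invisible(x)
}

#' Published screening counts of the field cohort
#'
#' The patient counts the study prints for its 3,102 screened diabetic
#' patients: positives per grader (AI 1,011 = 32.59%; ophthalmologist
#' 513 = 16.54%) and the consistent diagnoses (503 DR, 2,381 no-DR,
#' giving the 92.97% coincidence rate). Note these printed counts are
#' internally inconsistent as a 2x2 table: the disagreement cells
#' implied by the margins (508 + 10) exceed `n - a - d = 218`, so no
#' consistent completion exists and the study's printed kappa (0.780)
#' cannot be reproduced from them; each statistic must be computed from
#' the counts that define it, as the study did.
#'
#' @return List with `n`, `positives` (named: `ai`, `ophthalmologist`)
#'   and `consistent` (named: `DR`, `NDR`).
#' @export
dr_screening_counts <- function() {
  list(n = 3102,
       positives = c(ai = 1011, ophthalmologist = 513),
       consistent = c(DR = 503, NDR = 2381))
}
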