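#' Health states of the diabetic retinopathy Markov model
#'
#' The model tracks a closed cohort of diabetic patients over seven mutually
#' exclusive health states ordered by disease severity: no retinopathy (NDR),
#' mild, moderate and severe non-proliferative diabetic retinopathy (NPDR),
#' proliferative diabetic retinopathy (PDR), blindness, and death. Disease
#' can only stay put or progress one step per annual cycle; death is
#' reachable from every state and absorbing; recovery is not modelled.
#'
#' @return Character vector of the seven state labels, in their fixed
#'   ordinal order (NDR first, death last).
#' @examples
#' health_states()
#' @export
health_states <- function() {
  c("NDR", "mild_NPDR", "moderate_NPDR", "severe_NPDR", "PDR",
    "blindness", "dead")
}

# index helpers (1-based); alive = everything but dead
N_STATES <- 7L
ALIVE_STATES <- 1:6
NONBLIND_ALIVE <- 1:5
BLIND <- 6L
DEAD <- 7L

state_index <- function(label) {
  i <- match(label, health_states())
  if (anyNA(i)) {
    stop("unknown health state(s): ", paste(label[is.na(i)], collapse = ", "))
  }
  i
}

#' @keywords internal
check_probability <- function(x, name, min = 0, max = 1) {
  if (!is.numeric(x) || anyNA(x) || any(x < min) || any(x > max)) {
    stop(sprintf("'%s' must be numeric in [%g, %g]", name, min, max),
         call. = FALSE)
  }
  invisible(x)
}
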