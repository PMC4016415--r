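#' Health state space
#'
#' The model works on six aggregated clinical risk group (CRG) core health
#' statuses plus an explicit absorbing death state, in a fixed order that is
#' used consistently by every matrix, sampler and report in the package:
#' \code{E1} (healthy), \code{E2} (significant acute disease), \code{E34}
#' (minor chronic disease), \code{E56} (significant chronic disease in one or
#' two organ systems), \code{E79} (significant chronic disease in three or
#' more organ systems / catastrophic conditions), \code{E8} (dominant and
#' metastatic malignancies), and \code{DEAD}.
#'
#' @return `health_states()` returns the 7 state labels in their fixed order;
#'   `transient_states()` the 6 non-absorbing labels; `chronic_states()` the
#'   4 chronic labels (`E34`, `E56`, `E79`, `E8`); `genders()` the two gender
#'   labels `"F"` and `"M"`.
#' @examples
#' health_states()
#' chronic_states()
#' @export
health_states <- function() {
  c("E1", "E2", "E34", "E56", "E79", "E8", "DEAD")
}

#' @rdname health_states
#' @export
transient_states <- function() {
  c("E1", "E2", "E34", "E56", "E79", "E8")
}

#' @rdname health_states
#' @export
chronic_states <- function() {
  c("E34", "E56", "E79", "E8")
}

#' @rdname health_states
#' @export
genders <- function() {
  c("F", "M")
}

# number of states (m = 7, death included)
n_states <- function() 7L

#' Age-band scheme
#'
#' Transition matrices are stratified by gender and ten age bands. Bands are
#' half-open intervals \code{[lo, hi)} on completed years of age:
#' \code{[0,1), [1,15), [15,25), [25,35), [35,45), [45,55), [55,65), [65,75),
#' [75,85), [85,Inf)}, so every non-negative integer age maps to exactly one
#' band.
#'
#' @return `age_breaks()` returns the 10 lower bounds; `age_group_labels()`
#'   returns the 10 band labels.
#' @export
age_breaks <- function() {
  c(0L, 1L, 15L, 25L, 35L, 45L, 55L, 65L, 75L, 85L)
}

#' @rdname age_breaks
#' @export
age_group_labels <- function() {
  c("0", "1-14", "15-24", "25-34", "35-44", "45-54", "55-64", "65-74",
    "75-84", "85+")
}

#' Map completed age to its age band
#'
#' @param age integer vector of completed years of age (\eqn{\ge 0}).
#' @return Integer vector of band indices in `1:10` (band 1 is `[0,1)`,
#'   band 10 is `[85, Inf)`).
#' @examples
#' age_to_group(c(0, 14, 15, 85, 104))
#' @export
age_to_group <- function(age) {
  if (length(age) == 0L) return(integer(0))
  if (any(is.na(age)) || any(age < 0) || any(age != floor(age))) {
    stop("age must be a non-negative integer (completed years)")
  }
  findInterval(age, age_breaks())
}

# coerce a state label vector to indices 1..7, error on unknown labels
state_index <- function(state) {
  idx <- match(state, health_states())
  if (anyNA(idx)) {
    bad <- unique(state[is.na(idx)])
    stop("unknown state label(s): ", paste(bad, collapse = ", "))
  }
  idx
}

gender_index <- function(gender) {
  idx <- match(gender, genders())
  if (anyNA(idx)) {
    bad <- unique(gender[is.na(idx)])
    stop("unknown gender label(s): ", paste(bad, collapse = ", "))
  }
  idx
}
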