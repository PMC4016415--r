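#' Construct a stratified transition-matrix set
#'
#' The core container for one-year transition probabilities: a 7x7
#' row-stochastic matrix for each of the 20 strata (2 genders x 10 age
#' bands). Rows and columns follow the fixed state order of
#' [health_states()]; the `DEAD` row is always the unit vector on `DEAD`
#' (death is absorbing).
#'
#' @param p a 4-d numeric array with dimensions
#'   `(gender = 2, age_group = 10, from = 7, to = 7)`.
#' @param provenance character note on how the set was obtained (e.g.
#'   `"pooled"` or `"period 2004-2005"`).
#' @return An object of class `transition_matrix_set`.
#' @export
transition_matrix_set <- function(p, provenance = "pooled") {
  stopifnot(is.array(p), length(dim(p)) == 4L)
  if (!all(dim(p) == c(2L, 10L, n_states(), n_states()))) {
    stop("expected dimensions (2 genders, 10 age bands, 7 states, 7 states)")
  }
  dimnames(p) <- list(gender = genders(), age_group = age_group_labels(),
                      from = health_states(), to = health_states())
  if (any(is.na(p)) || any(p < -1e-12) || any(p > 1 + 1e-12)) {
    stop("transition probabilities must lie in [0, 1]")
  }
  rs <- apply(p, c(1, 2, 3), sum)
  if (any(abs(rs - 1) > 1e-10)) {
    bad <- which(abs(rs - 1) > 1e-10, arr.ind = TRUE)[1, ]
    stop(sprintf("non-stochastic row: gender %s, band %s, from %s (sum %.12f)",
                 genders()[bad[1]], age_group_labels()[bad[2]],
                 health_states()[bad[3]], rs[bad[1], bad[2], bad[3]]))
  }
  dead <- n_states()
  dead_ok <- abs(p[, , dead, dead] - 1) < 1e-12
  if (!all(dead_ok)) stop("DEAD row must be the unit vector on DEAD")
  structure(p, class = "transition_matrix_set", provenance = provenance)
}

#' Extract one stratum matrix
#'
#' @param ms a `transition_matrix_set`.
#' @param gender `"F"` or `"M"`.
#' @param band age-band index in `1:10` (see [age_to_group()]).
#' @return The 7x7 row-stochastic matrix of the stratum.
#' @export
stratum_matrix <- function(ms, gender, band) {
  m <- ms[gender_index(gender), band, , ]
  dim(m) <- c(n_states(), n_states())
  dimnames(m) <- list(from = health_states(), to = health_states())
  m
}

#' Replicate one matrix across all strata
#'
#' Builds an age- and gender-homogeneous `transition_matrix_set` from a
#' single 7x7 matrix. Useful for toy chains where closed-form results
#' (geometric sojourns, the fundamental matrix) are available.
#'
#' @param P a 7x7 row-stochastic matrix in the fixed state order.
#' @inheritParams transition_matrix_set
#' @return A `transition_matrix_set`.
#' @export
homogeneous_matrix_set <- function(P, provenance = "homogeneous") {
  stopifnot(is.matrix(P), all(dim(P) == n_states()))
  p <- array(0, dim = c(2L, 10L, n_states(), n_states()))
  for (i in seq_len(n_states())) for (j in seq_len(n_states())) {
    p[, , i, j] <- P[i, j]
  }
  transition_matrix_set(p, provenance = provenance)
}

#' @export
print.transition_matrix_set <- function(x, ...) {
  cat(sprintf("transition matrix set: 20 strata (2 genders x 10 age bands), %s\n",
              attr(x, "provenance")))
  invisible(x)
}

#' Write a matrix set to CSV
#'
#' Long format with columns `gender, age_group, from_state, to_state,
#' probability`; probabilities carry 12 decimals so the round-trip through
#' [read_matrix_set()] is exact to that precision.
#'
#' @param ms a `transition_matrix_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix_set <- function(ms, path) {
  grid <- expand.grid(to_state = health_states(), from_state = health_states(),
                      age_group = age_group_labels(), gender = genders(),
                      stringsAsFactors = FALSE)
  grid <- grid[, c("gender", "age_group", "from_state", "to_state")]
  prob <- mapply(function(g, a, i, j) {
    ms[gender_index(g), match(a, age_group_labels()),
       state_index(i), state_index(j)]
  }, grid$gender, grid$age_group, grid$from_state, grid$to_state)
  grid$probability <- sprintf("%.12f", prob)
  utils::write.csv(grid, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a matrix set from CSV
#'
#' @param path a file written by [write_matrix_set()].
#' @return A `transition_matrix_set`.
#' @export
read_matrix_set <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("gender", "age_group", "from_state", "to_state", "probability")
  if (!all(required %in% names(d))) {
    stop("matrix set file must have columns ", paste(required, collapse = ", "))
  }
  p <- array(NA_real_, dim = c(2L, 10L, n_states(), n_states()))
  idx <- cbind(gender_index(d$gender), match(d$age_group, age_group_labels()),
               state_index(d$from_state), state_index(d$to_state))
  if (anyNA(idx)) stop("unknown age-band label in matrix set file")
  p[idx] <- d$probability
  if (anyNA(p)) stop("matrix set file does not cover all 980 cells")
  # tidy float fuzz from the 12-decimal text representation (but do not
  # rescue genuinely non-stochastic rows)
  rs <- apply(p, c(1, 2, 3), sum)
  if (any(abs(rs - 1) > 1e-10)) stop("non-stochastic row in matrix set file")
  p <- sweep(p, c(1, 2, 3), rs, "/")
  transition_matrix_set(p, provenance = sprintf("read from %s", path))
}
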