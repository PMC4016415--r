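#' Construct and validate an initial cohort mix
#'
#' Probability distribution over (gender, transient state) at birth.
#'
#' @param mix 2x6 numeric matrix (rows `F`, `M`; columns the transient
#'   states in fixed order) summing to 1.
#' @return The validated matrix with canonical dimnames.
#' @export
initial_mix <- function(mix) {
  stopifnot(is.matrix(mix), all(dim(mix) == c(2L, 6L)))
  if (any(mix < 0) || abs(sum(mix) - 1) > 1e-8) {
    stop("initial mix must be non-negative and sum to 1")
  }
  dimnames(mix) <- list(gender = genders(), state = transient_states())
  mix
}

#' Estimate the initial mix from a panel's infant cross-section
#'
#' Takes the (gender, state) frequencies of the records aged under 1 —
#' the cohort entry structure of the modelled population. By default all
#' panel years are pooled (infants are scarce in any single year); a
#' single reference year can be requested instead.
#'
#' @param panel a [person_year_panel()].
#' @param year optional reference calendar year (default: pool all years).
#' @return A 2x6 probability matrix as in [initial_mix()].
#' @export
initial_mix_from_panel <- function(panel, year = NULL) {
  d <- as.data.frame(panel)
  if (!is.null(year)) d <- d[d$year == year, , drop = FALSE]
  d <- d[d$age == 0L & d$state != "DEAD", , drop = FALSE]
  if (!nrow(d)) stop("no infant (age 0) records in the panel")
  tab <- table(factor(d$gender, levels = genders()),
               factor(d$state, levels = transient_states()))
  initial_mix(unclass(tab) / sum(tab))
}

#' Exact cohort propagation through the stratified chain
#'
#' Propagates the expected state occupancy of a closed birth cohort
#' through the gender- and age-stratified one-year transition matrices:
#' `mass(age+1) = mass(age) %*% P(gender, band(age))`. Occupancy is
#' real-valued (expected counts, no rounding) and measured at the start of
#' each year of age. Iteration stops when the surviving mass drops below
#' `extinction_tol` of the cohort size or at `max_age`, at which point all
#' surviving mass is forced to `DEAD`.
#'
#' @param matrices a [transition_matrix_set()].
#' @param mix an [initial_mix()] (or the `initial_mix` of a ground truth).
#' @param size initial cohort size (default 100,000).
#' @param max_age hard age cap with forced death (default 110).
#' @param extinction_tol surviving-mass fraction below which the cohort is
#'   declared extinct (default 1e-6).
#' @return An object of class `cohort_occupancy`: list with `mass` (array
#'   `(age, gender, state)` of expected counts, ages `0..A`), `ages`,
#'   `size`, and `initial` (per-gender initial mass).
#' @export
run_cohort <- function(matrices, mix, size = 1e5, max_age = 110L,
                       extinction_tol = 1e-6) {
  stopifnot(inherits(matrices, "transition_matrix_set"))
  mix <- initial_mix(mix)
  if (size <= 0) stop("cohort size must be positive")
  if (max_age < 1L) stop("max_age must be >= 1")
  cur <- rbind(c(size * mix[1L, ], 0), c(size * mix[2L, ], 0))
  rows <- list()
  a <- 0L
  repeat {
    rows[[a + 1L]] <- cur
    alive <- sum(cur[, 1:6])
    if (alive < extinction_tol * size || a >= max_age) break
    band <- age_to_group(a)
    nxt <- cur
    for (g in 1:2) {
      P <- matrices[g, band, , ]
      nxt[g, ] <- as.vector(cur[g, ] %*% P)
    }
    cur <- nxt
    a <- a + 1L
  }
  # force any surviving mass to DEAD in a terminal row
  if (sum(rows[[length(rows)]][, 1:6]) > 0) {
    final <- rows[[length(rows)]]
    dead_only <- matrix(0, 2L, n_states())
    dead_only[, n_states()] <- rowSums(final)
    rows[[length(rows) + 1L]] <- dead_only
  }
  mass <- array(0, dim = c(length(rows), 2L, n_states()),
                dimnames = list(age = seq_along(rows) - 1L,
                                gender = genders(), state = health_states()))
  for (i in seq_along(rows)) mass[i, , ] <- rows[[i]]
  structure(list(mass = mass, ages = seq_along(rows) - 1L, size = size,
                 initial = rowSums(mass[1L, , , drop = FALSE][1, , ])),
            class = "cohort_occupancy")
}

#' @export
print.cohort_occupancy <- function(x, ...) {
  cat(sprintf(
    "cohort occupancy: size %g, ages 0-%d, terminal surviving mass %.3g\n",
    x$size, max(x$ages), sum(x$mass[length(x$ages), , 1:6])))
  invisible(x)
}

#' Expected years of life per (gender, state)
#'
#' Under the start-of-year occupancy convention each surviving start of a
#' year of age contributes one person-year to its state, so the expected
#' years in a state are the age-summed occupancy divided by the initial
#' gender mass.
#'
#' @param occ a `cohort_occupancy` from [run_cohort()].
#' @return 2x6 matrix of expected years (rows `F`, `M`).
#' @export
expected_years <- function(occ) {
  totals <- apply(occ$mass[, , 1:6, drop = FALSE], c(2, 3), sum)
  ey <- sweep(totals, 1L, occ$initial, "/")
  ey[occ$initial == 0, ] <- NA_real_
  dimnames(ey) <- list(gender = genders(), state = transient_states())
  ey
}

#' Mean annual cost per survivor by age
#'
#' For each age and gender, the occupancy-weighted mean of the cell costs
#' over the transient states, divided by the surviving mass at that age.
#' Ages without survivors yield `NA` (missing, not zero).
#'
#' @param occ a `cohort_occupancy`.
#' @param costs a [cost_table()] covering all transient states.
#' @return data.frame with columns `age`, `gender`, `mean_cost`.
#' @export
yearly_mean_cost <- function(occ, costs) {
  out <- expand.grid(age = occ$ages, gender = genders(),
                     stringsAsFactors = FALSE)
  out$mean_cost <- NA_real_
  for (g in 1:2) {
    band <- age_to_group(occ$ages)
    cmat <- matrix(cost_lookup(costs, genders()[g],
                               rep(band, times = 6L),
                               rep(transient_states(), each = length(occ$ages))),
                   nrow = length(occ$ages))
    num <- rowSums(occ$mass[, g, 1:6, drop = FALSE][, 1, ] * cmat)
    den <- rowSums(occ$mass[, g, 1:6, drop = FALSE][, 1, ])
    v <- ifelse(den > 0, num / den, NA_real_)
    out$mean_cost[out$gender == genders()[g]] <- v
  }
  out
}

#' Mean lifetime cost per gender
#'
#' Aggregates the whole projection: the occupancy-weighted cost summed
#' over all ages and transient states, divided by the initial gender mass.
#' With an age-invariant cost table this equals
#' `sum_s expected_years(g, s) * cost(g, s)` exactly.
#'
#' @inheritParams yearly_mean_cost
#' @return Named numeric vector `c(F = ..., M = ...)` in euros.
#' @export
lifetime_mean_cost <- function(occ, costs) {
  out <- c(F = NA_real_, M = NA_real_)
  band <- age_to_group(occ$ages)
  for (g in 1:2) {
    cmat <- matrix(cost_lookup(costs, genders()[g],
                               rep(band, times = 6L),
                               rep(transient_states(), each = length(occ$ages))),
                   nrow = length(occ$ages))
    tot <- sum(occ$mass[, g, 1:6, drop = FALSE][, 1, ] * cmat)
    out[g] <- if (occ$initial[g] > 0) tot / occ$initial[g] else NA_real_
  }
  out
}

#' Bundle the cohort-engine outputs
#'
#' @inheritParams yearly_mean_cost
#' @return List of class `cohort_result`: `occupancy`, `expected_years`
#'   (2x6), `total_le` (per gender), `yearly_mean_cost` (data.frame) and
#'   `lifetime_mean_cost` (per gender); cost elements are `NULL` when no
#'   cost table is given.
#' @export
cohort_result <- function(occ, costs = NULL) {
  ey <- expected_years(occ)
  res <- list(occupancy = occ, expected_years = ey,
              total_le = rowSums(ey),
              yearly_mean_cost = if (!is.null(costs)) yearly_mean_cost(occ, costs),
              lifetime_mean_cost = if (!is.null(costs)) lifetime_mean_cost(occ, costs))
  class(res) <- "cohort_result"
  res
}

#' @export
print.cohort_result <- function(x, ...) {
  cat("cohort projection\n  life expectancy at birth: ",
      paste(sprintf("%s %.2f", genders(), x$total_le), collapse = ", "), "\n",
      sep = "")
  if (!is.null(x$lifetime_mean_cost)) {
    cat("  mean lifetime cost: ",
        paste(sprintf("%s %.2f", genders(), x$lifetime_mean_cost),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Write cohort occupancy to CSV
#'
#' Long format `age, gender, state, mass`.
#'
#' @param occ a `cohort_occupancy`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_occupancy <- function(occ, path) {
  grid <- expand.grid(age = occ$ages, gender = genders(),
                      state = health_states(), stringsAsFactors = FALSE)
  grid$mass <- as.vector(occ$mass)
  utils::write.csv(grid, path, row.names = FALSE)
  invisible(path)
}
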