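# cumulative rows per (gender, band, origin) key, final boundary pinned to 1
cumulative_rows <- function(matrices) {
  cum <- matrix(0, 2L * 10L * 7L, n_states())
  for (g in 1:2) for (a in 1:10) for (i in 1:7) {
    cum[(g - 1L) * 70L + (a - 1L) * 7L + i, ] <-
      cumsum(matrices[g, a, i, ])
  }
  cum[, n_states()] <- 1
  cum
}

#' Draw initial (gender, state) pairs from a mix
#'
#' Inverse-CDF draw over the 12 (gender, transient state) cells of an
#' initial mix, scanning genders then states in fixed order with half-open
#' boundaries.
#'
#' @param mix an [initial_mix()].
#' @param n number of draws.
#' @return data.frame with columns `gender` and `state`.
#' @export
draw_initial_state <- function(mix, n = 1L) {
  mix <- initial_mix(mix)
  cells <- as.vector(t(mix))        # F states 1..6, then M states 1..6
  cum <- matrix(cumsum(cells), n, 12L, byrow = TRUE)
  cum[, 12L] <- 1
  k <- draw_categorical(cum, stats::runif(n))
  data.frame(gender = genders()[(k - 1L) %/% 6L + 1L],
             state = transient_states()[(k - 1L) %% 6L + 1L],
             stringsAsFactors = FALSE)
}

#' Simulate one birth-to-death pathway
#'
#' Generates a single lifetime state sequence: starting from a transient
#' state at age 0, the next state is sampled each year by comparing one
#' pseudo-random uniform to the cumulative transition probabilities of the
#' origin row (fixed state order, half-open boundaries), until death or
#' the `max_age` cap with forced death.
#'
#' @param matrices a [transition_matrix_set()].
#' @param gender `"F"` or `"M"`.
#' @param initial_state a transient state label.
#' @param max_age hard age cap (default 110).
#' @return Character vector of transient states by age (age 0 first); the
#'   pathway length is the number of years lived.
#' @export
simulate_pathway <- function(matrices, gender, initial_state,
                             max_age = 110L) {
  stopifnot(inherits(matrices, "transition_matrix_set"))
  g <- gender_index(gender)
  s <- state_index(initial_state)
  if (s == n_states()) stop("initial state must be transient")
  states <- integer(0)
  a <- 0L
  while (s != n_states() && a <= max_age) {
    states <- c(states, s)
    cum <- cumsum(matrices[g, age_to_group(a), s, ])
    cum[n_states()] <- 1
    s <- sum(cum <= stats::runif(1L)) + 1L
    a <- a + 1L
  }
  health_states()[states]
}

#' Simulate a collection of individual pathways
#'
#' Vectorized microsimulation of `n_per_gender` birth-to-death pathways
#' per gender. Initial states are drawn from the gender-conditional
#' initial mix; each simulated year contributes the cost-table cell mean
#' for the current (gender, age band, state) to the lifetime cost (no
#' individual-level cost noise, so cost variability across pathways
#' reflects the variability of health transitions).
#'
#' @param matrices a [transition_matrix_set()].
#' @param mix an [initial_mix()].
#' @param n_per_gender pathways per gender (default 10,000).
#' @param costs optional [cost_table()]; without it lifetime costs are 0.
#' @param seed integer seed making the collection reproducible.
#' @param max_age hard age cap with forced death (default 110).
#' @return An object of class `pathway_collection`: list with `gender`
#'   (per pathway), `states` (integer matrix, one row per pathway, columns
#'   ages 0..`max_age`, `NA` after death), `years` (pathway x 6 matrix of
#'   years per state), `lifetime_cost`, `n_per_gender`, `seed`.
#' @export
simulate_collection <- function(matrices, mix, n_per_gender = 10000L,
                                costs = NULL, seed = 1L, max_age = 110L) {
  stopifnot(inherits(matrices, "transition_matrix_set"))
  mix <- initial_mix(mix)
  if (n_per_gender < 1L) stop("n_per_gender must be >= 1")
  set.seed(seed)
  n <- 2L * n_per_gender
  g_idx <- rep(1:2, each = n_per_gender)
  state <- integer(n)
  for (g in 1:2) {
    p <- mix[g, ] / sum(mix[g, ])
    cum <- matrix(cumsum(p), n_per_gender, 6L, byrow = TRUE)
    cum[, 6L] <- 1
    state[g_idx == g] <- draw_categorical(cum, stats::runif(n_per_gender))
  }
  cum_rows <- cumulative_rows(matrices)
  states <- matrix(NA_integer_, n, max_age + 1L)
  years <- matrix(0L, n, 6L, dimnames = list(NULL, transient_states()))
  cost_acc <- numeric(n)
  alive <- seq_len(n)
  for (a in 0:max_age) {
    states[cbind(alive, a + 1L)] <- state[alive]
    years[cbind(alive, state[alive])] <- years[cbind(alive, state[alive])] + 1L
    if (!is.null(costs)) {
      cost_acc[alive] <- cost_acc[alive] +
        cost_lookup(costs, genders()[g_idx[alive]], age_to_group(a),
                    health_states()[state[alive]])
    }
    if (a == max_age) break
    key <- (g_idx[alive] - 1L) * 70L + (age_to_group(a) - 1L) * 7L +
      state[alive]
    nxt <- draw_categorical(cum_rows[key, , drop = FALSE],
                            stats::runif(length(alive)))
    state[alive] <- nxt
    alive <- alive[nxt != n_states()]
    if (!length(alive)) break
  }
  structure(list(gender = genders()[g_idx], states = states, years = years,
                 lifetime_cost = cost_acc, n_per_gender = n_per_gender,
                 seed = seed, max_age = max_age),
            class = "pathway_collection")
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat(sprintf(
    "pathway collection: %d pathways per gender (seed %d), mean length %.2f\n",
    x$n_per_gender, x$seed, mean(rowSums(x$years))))
  invisible(x)
}

# central moments helper
central_moment <- function(x, k) mean((x - mean(x))^k)

#' Summarize the lifetime-cost distribution
#'
#' Moment and quantile summary of the lifetime costs of one gender's
#' pathways: mean, sample SD and variance, skewness (third standardized
#' central moment), kurtosis in both the raw and the excess convention,
#' extremes, and linearly interpolated quartiles.
#'
#' @param collection a `pathway_collection`.
#' @param gender `"F"` or `"M"`.
#' @return One-row data.frame with columns `gender`, `n_trials`, `mean`,
#'   `sd`, `variance`, `skewness`, `kurtosis_raw`, `kurtosis_excess`,
#'   `min`, `max`, `p25`, `p50`, `p75`.
#' @export
summarize_costs <- function(collection, gender) {
  x <- collection$lifetime_cost[collection$gender == gender]
  if (!length(x)) stop("no pathways for gender ", gender)
  if (length(x) < 2L) stop("at least two pathways are needed for an SD")
  s <- stats::sd(x)
  m2 <- central_moment(x, 2)
  if (m2 > 0) {
    skew <- central_moment(x, 3) / m2^1.5
    kurt <- central_moment(x, 4) / m2^2
  } else {
    skew <- NA_real_; kurt <- NA_real_
  }
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  data.frame(gender = gender, n_trials = length(x), mean = mean(x), sd = s,
             variance = s^2, skewness = skew, kurtosis_raw = kurt,
             kurtosis_excess = kurt - 3, min = min(x), max = max(x),
             p25 = q[1L], p50 = q[2L], p75 = q[3L],
             stringsAsFactors = FALSE)
}

#' Summarize years spent per state
#'
#' Mean, SD, min and max of the years spent in each transient state across
#' the pathways of each gender (pathways that never visit a state count as
#' 0 years). Per gender, the state means sum to the mean pathway length.
#'
#' @param collection a `pathway_collection`.
#' @return data.frame with one row per (gender, state): `gender`, `state`,
#'   `mean`, `sd`, `min`, `max`.
#' @export
summarize_years <- function(collection) {
  rows <- list()
  for (g in genders()) {
    y <- collection$years[collection$gender == g, , drop = FALSE]
    for (s in seq_len(6L)) {
      rows[[length(rows) + 1L]] <- data.frame(
        gender = g, state = transient_states()[s],
        mean = mean(y[, s]), sd = stats::sd(y[, s]),
        min = min(y[, s]), max = max(y[, s]), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Export pathways to CSV
#'
#' Long format `pathway_id, gender, age, state, cost` (one row per lived
#' year; the cost column is the attached cell mean).
#'
#' @param collection a `pathway_collection`.
#' @param costs the [cost_table()] used during simulation (or `NULL` for
#'   zero costs).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pathways <- function(collection, costs, path) {
  idx <- which(!is.na(collection$states), arr.ind = TRUE)
  d <- data.frame(pathway_id = idx[, 1L],
                  gender = collection$gender[idx[, 1L]],
                  age = idx[, 2L] - 1L,
                  state = health_states()[collection$states[idx]],
                  stringsAsFactors = FALSE)
  d <- d[order(d$pathway_id, d$age), , drop = FALSE]
  d$cost <- if (is.null(costs)) 0 else
    cost_lookup(costs, d$gender, age_to_group(d$age), d$state)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
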