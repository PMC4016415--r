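#' Configuration for the synthetic registry generator
#'
#' Bundles and validates the knobs of the synthetic-registry generator. The
#' defaults emulate the statistical shape of a county-level integrated-care
#' registry: roughly 89,000 residents observed over four calendar years,
#' two-thirds of the cross-section healthy, an infant acute-care peak, an
#' excess of acute episodes among women of childbearing age (15-44),
#' mortality increasing with both age and morbidity severity, and
#' right-skewed annual costs.
#'
#' @param n_individuals number of individuals present in the first year.
#' @param years calendar years of observation (at least 2).
#' @param seed root seed; three independent sub-streams (population
#'   structure and migration, state dynamics, costs) are derived from it so
#'   that toggling cost generation does not perturb state paths.
#' @param severity_gradient exponent on the per-state mortality multipliers
#'   (>0; 1 keeps the built-in severity ladder).
#' @param age_mortality_gradient multiplicative growth of the baseline
#'   mortality hazard from one age band to the next (>0; >=1 keeps
#'   mortality non-decreasing in age).
#' @param female_acute_multiplier factor on the healthy-to-acute transition
#'   for women in the 15-24, 25-34 and 35-44 bands (>0; default 1.5,
#'   motivated by pregnancy-related acute episodes).
#' @param cost_cv coefficient of variation of the annual cost draws
#'   (0 = deterministic cell means).
#' @param migration_out_rate per-year probability that an individual leaves
#'   observation (censoring without a death record).
#' @param migration_in_rate yearly inflow of new individuals, as a fraction
#'   of `n_individuals`.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_individuals = 88858L,
                         years = 2004:2007,
                         seed = 1L,
                         severity_gradient = 1,
                         age_mortality_gradient = 2.7,
                         female_acute_multiplier = 1.5,
                         cost_cv = 1.5,
                         migration_out_rate = 0.02,
                         migration_in_rate = 0.02) {
  years <- as.integer(years)
  if (n_individuals < 1L) stop("n_individuals must be >= 1")
  if (length(years) < 2L || any(diff(years) != 1L)) {
    stop("years must be at least two consecutive calendar years")
  }
  if (severity_gradient <= 0 || age_mortality_gradient <= 0 ||
      female_acute_multiplier <= 0) {
    stop("gradients and multipliers must be positive")
  }
  if (cost_cv < 0) stop("cost_cv must be >= 0")
  if (migration_out_rate < 0 || migration_out_rate >= 1 ||
      migration_in_rate < 0 || migration_in_rate >= 1) {
    stop("migration rates must lie in [0, 1)")
  }
  structure(list(n_individuals = as.integer(n_individuals), years = years,
                 seed = as.integer(seed),
                 severity_gradient = severity_gradient,
                 age_mortality_gradient = age_mortality_gradient,
                 female_acute_multiplier = female_acute_multiplier,
                 cost_cv = cost_cv,
                 migration_out_rate = migration_out_rate,
                 migration_in_rate = migration_in_rate),
            class = "synth_config")
}

#' Read a generator configuration from a YAML file
#'
#' @param path YAML file whose top-level keys match the arguments of
#'   [synth_config()].
#' @return A `synth_config`.
#' @export
read_synth_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read config files")
  }
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$years) && length(vals$years) == 2L &&
      !is.null(names(vals$years))) {
    vals$years <- seq(vals$years[["from"]], vals$years[["to"]])
  }
  do.call(synth_config, vals)
}

# age-band population shares of the emulated county register (10 bands)
pyramid_shares <- function() {
  c(0.0108, 0.1435, 0.1117, 0.1778, 0.1686, 0.1290, 0.0976, 0.0791,
    0.0612, 0.0207)
}

# draw integer ages from the band pyramid, uniform within band (85+ -> 85-99)
draw_pyramid_ages <- function(n) {
  lo <- age_breaks()
  hi <- c(age_breaks()[-1L], 100L)
  band <- sample.int(10L, n, replace = TRUE, prob = pyramid_shares())
  lo[band] + floor(stats::runif(n) * (hi[band] - lo[band]))
}

# baseline one-year mortality by (gender, band, state); non-decreasing in band
mortality_grid <- function(config) {
  q1 <- 2e-5
  sev <- c(1, 1.5, 1.3, 1.8, 6, 14)^config$severity_gradient
  # age-independent excess hazard of the severe states (short sojourns in
  # the catastrophic and malignancy groups at any age)
  floor_q <- c(0, 0, 0, 0.002, 0.04, 0.15)
  gender_factor <- c(F = 0.8, M = 1)
  q <- array(0, dim = c(2L, 10L, 6L))
  for (g in 1:2) for (a in 1:10) {
    base <- q1 * config$age_mortality_gradient^(a - 1) * sev *
      gender_factor[g]
    q[g, a, ] <- pmin(0.9, pmax(floor_q, base))
  }
  q
}

# transient-destination weights for one (gender, band) stratum; rows are
# origin states E1..E8, columns destinations E1..E8 (unnormalized)
transient_weights <- function(config, g, a) {
  fem <- if (g == 1L && a %in% 3:5) config$female_acute_multiplier else 1
  male <- if (g == 2L) 1.3 else 1   # men reach the top severity groups more
  band_acute <- c(4, 1.2, 1, 1, 1, 1, 1.2, 1.4, 1.8, 2.2)[a]
  ramp <- function(base, slope) base * (1 + slope * (a - 1))
  w <- matrix(0, 6L, 6L, dimnames = list(transient_states(),
                                         transient_states()))
  w["E1", ] <- c(0.90, 0.05 * band_acute * fem, ramp(0.016, 0.25),
                 ramp(0.014, 0.45), ramp(0.00015, 0.5) * male,
                 ramp(0.00008, 0.5) * male)
  w["E2", ] <- c(0.65, 0.12, ramp(0.04, 0.20), ramp(0.05, 0.30),
                 ramp(0.0008, 0.4) * male, ramp(0.0004, 0.4) * male)
  w["E34", ] <- c(0.24, 0.03, 0.62, ramp(0.06, 0.30), ramp(0.0008, 0.4),
                  0.0004)
  w["E56", ] <- c(0.10, 0.02, 0.05, 0.77, ramp(0.0025, 0.4) * male,
                  0.001 * male)
  w["E79", ] <- c(0.01, 0.01, 0.01, 0.22, 0.70, 0.01)
  w["E8", ] <- c(0.01, 0.01, 0.005, 0.10, 0.03, 0.70)
  w
}

#' Build a known-true transition structure and cost model
#'
#' Constructs the synthetic ground truth: 20 row-stochastic 7x7 transition
#' matrices (2 genders x 10 age bands) with an absorbing death state, an
#' initial (birth) state mix, a right-skewed cost model, and migration
#' rates. The construction guarantees, for any valid configuration, that
#' mortality is non-decreasing across age bands within each (gender,
#' state), and that the healthy-to-acute probability for women exceeds the
#' male value in the 15-44 bands.
#'
#' @param config a [synth_config()].
#' @return A list of class `ground_truth` with elements `matrices`
#'   (a [transition_matrix_set()]), `initial_mix` (2x6 probability matrix
#'   over gender x transient state at birth), `cost_model` (list with
#'   `means` 2x6 and `cv`), and `migration` (in/out rates).
#' @export
make_ground_truth <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  q <- mortality_grid(config)
  p <- array(0, dim = c(2L, 10L, n_states(), n_states()))
  for (g in 1:2) for (a in 1:10) {
    w <- transient_weights(config, g, a)
    for (i in 1:6) {
      p[g, a, i, 1:6] <- (1 - q[g, a, i]) * w[i, ] / sum(w[i, ])
      p[g, a, i, 7L] <- q[g, a, i]
    }
    p[g, a, 7L, 7L] <- 1
  }
  # birth mix: ~96% healthy, slight male majority, same state mix per gender
  state_mix <- c(E1 = 0.96, E2 = 0.03, E34 = 0.004, E56 = 0.004,
                 E79 = 0.001, E8 = 0.001)
  gender_share <- c(F = 0.495, M = 0.505)
  mix <- outer(gender_share, state_mix)
  dimnames(mix) <- list(gender = genders(), state = transient_states())
  structure(list(matrices = transition_matrix_set(p, "synthetic ground truth"),
                 initial_mix = mix,
                 cost_model = list(means = reference_cost_means(),
                                   cv = config$cost_cv),
                 migration = list(out_rate = config$migration_out_rate,
                                  in_rate = config$migration_in_rate)),
            class = "ground_truth")
}

#' Sample right-skewed annual costs
#'
#' Draws annual costs from a gamma family parameterized by the cell mean
#' and a coefficient of variation: `shape = 1/cv^2`, `scale = mean*cv^2`,
#' so the expectation equals the configured (gender, state) mean exactly
#' and the distribution is right-skewed for any `cv > 0`. With `cv = 0`
#' every draw equals the mean.
#'
#' @param gender character vector of `"F"`/`"M"` (recycled).
#' @param state character vector of transient state labels (recycled);
#'   `DEAD` is rejected.
#' @param cost_model list with `means` (2x6 matrix) and `cv`, as in the
#'   `cost_model` element of [make_ground_truth()].
#' @param n number of draws (defaults to the recycled vector length).
#' @return Numeric vector of euro amounts.
#' @export
sample_annual_cost <- function(gender, state,
                               cost_model = list(means = reference_cost_means(),
                                                 cv = 1.5),
                               n = NULL) {
  if (is.null(n)) n <- max(length(gender), length(state))
  gender <- rep_len(gender, n); state <- rep_len(state, n)
  if (any(state == "DEAD")) stop("no cost can be drawn for the DEAD state")
  mu <- cost_model$means[cbind(gender_index(gender),
                               match(state, transient_states()))]
  if (anyNA(mu)) stop("unknown state label in cost draw")
  cv <- cost_model$cv
  if (cv == 0) return(mu)
  shape <- 1 / cv^2
  stats::rgamma(n, shape = shape, scale = mu / shape)
}

# conditional state distribution among survivors at each age, per gender,
# obtained by propagating the true chain from birth (ages 0..99)
conditional_state_dist <- function(truth, max_age = 99L) {
  dist <- array(0, dim = c(max_age + 1L, 2L, 6L))
  for (g in 1:2) {
    mass <- c(truth$initial_mix[g, ] / sum(truth$initial_mix[g, ]), 0)
    for (a in 0:max_age) {
      alive <- sum(mass[1:6])
      dist[a + 1L, g, ] <- if (alive > 0) mass[1:6] / alive else
        c(1, 0, 0, 0, 0, 0)
      P <- truth$matrices[g, age_to_group(a), , ]
      mass <- as.vector(mass %*% P)
    }
  }
  dist
}

# vectorized categorical draw: one uniform per row of a cumulative-prob
# matrix, half-open boundaries so each draw maps to exactly one column
draw_categorical <- function(cum, u) {
  rowSums(cum <= u) + 1L
}

#' Generate a synthetic person-year panel
#'
#' Simulates a longitudinal registry under a known ground truth: the state
#' of an individual in one year depends only on the state of the year
#' before (first-order Markov, by construction), deaths are recorded as
#' explicit `DEAD` records in the year of death, out-migration censors a
#' sequence without a death record, in-migrants enter in later years with
#' ages drawn from the population pyramid, and per-record costs are drawn
#' from the gamma cost model (rounded to cents). The same seed yields an
#' identical panel.
#'
#' @param truth a `ground_truth` from [make_ground_truth()].
#' @param config the [synth_config()] (supplies size, years and seed).
#' @param costs logical; attach a cost column? Disabling it does not
#'   change the simulated state paths.
#' @return A [person_year_panel()].
#' @export
generate_panel <- function(truth, config = synth_config(), costs = TRUE) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "synth_config"))
  set.seed(config$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 3L)
  years <- config$years
  n0 <- config$n_individuals

  # --- stream 1: population structure and migration -------------------
  set.seed(sub_seeds[1L])
  n_in_per_year <- round(truth$migration$in_rate * n0)
  n_total <- n0 + n_in_per_year * (length(years) - 1L)
  entry_year <- c(rep(years[1L], n0),
                  rep(years[-1L], each = n_in_per_year))
  age_at_entry <- draw_pyramid_ages(n_total)
  gender <- ifelse(stats::runif(n_total) < 0.505, "M", "F")
  # geometric out-migration clock: last calendar year under observation
  out_rate <- truth$migration$out_rate
  if (out_rate > 0) {
    yrs_observed <- stats::rgeom(n_total, out_rate) + 1L
  } else {
    yrs_observed <- rep(length(years), n_total)
  }
  exit_year <- entry_year + yrs_observed - 1L   # censoring after this year

  # --- stream 2: initial states and dynamics --------------------------
  set.seed(sub_seeds[2L])
  cond <- conditional_state_dist(truth)
  g_idx <- gender_index(gender)
  cum_init <- matrix(0, n_total, 6L)
  a_capped <- pmin(age_at_entry, 99L)
  for (k in seq_len(6L)) {
    cum_init[, k] <- if (k == 1L) cond[cbind(a_capped + 1L, g_idx, 1L)] else
      cum_init[, k - 1L] + cond[cbind(a_capped + 1L, g_idx, k)]
  }
  cum_init[, 6L] <- 1
  state0 <- draw_categorical(cum_init, stats::runif(n_total))

  # precompute cumulative transition rows per (gender, band, origin) key
  cum_rows <- matrix(0, 2L * 10L * 7L, n_states())
  for (g in 1:2) for (a in 1:10) for (i in 1:7) {
    key <- (g - 1L) * 70L + (a - 1L) * 7L + i
    cum_rows[key, ] <- cumsum(truth$matrices[g, a, i, ])
  }
  cum_rows[, n_states()] <- 1

  rec_person <- integer(0); rec_year <- integer(0); rec_age <- integer(0)
  rec_state <- integer(0); rec_gender <- character(0)
  cur_state <- state0
  retired <- logical(n_total)   # TRUE once the DEAD record has been emitted
  for (yi in seq_along(years)) {
    y <- years[yi]
    active <- which(entry_year <= y & exit_year >= y & !retired)
    if (length(active)) {
      age_now <- age_at_entry[active] + (y - entry_year[active])
      rec_person <- c(rec_person, active)
      rec_year <- c(rec_year, rep(y, length(active)))
      rec_age <- c(rec_age, age_now)
      rec_state <- c(rec_state, cur_state[active])
      rec_gender <- c(rec_gender, gender[active])
      retired[active[cur_state[active] == 7L]] <- TRUE
      if (yi < length(years)) {
        movers <- active[cur_state[active] != 7L]
        if (length(movers)) {
          a_now <- age_at_entry[movers] + (y - entry_year[movers])
          key <- (g_idx[movers] - 1L) * 70L +
            (age_to_group(a_now) - 1L) * 7L + cur_state[movers]
          cur_state[movers] <- draw_categorical(
            cum_rows[key, , drop = FALSE], stats::runif(length(movers)))
        }
      }
    }
  }

  panel <- data.frame(person_id = sprintf("P%06d", rec_person),
                      year = rec_year, gender = rec_gender,
                      age = rec_age,
                      state = health_states()[rec_state],
                      stringsAsFactors = FALSE)

  # --- stream 3: costs -------------------------------------------------
  if (costs) {
    set.seed(sub_seeds[3L])
    transient <- panel$state != "DEAD"
    panel$cost <- 0
    panel$cost[transient] <- round(sample_annual_cost(
      panel$gender[transient], panel$state[transient],
      truth$cost_model), 2)
  }
  person_year_panel(panel)
}
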