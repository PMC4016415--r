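#' Count stratified one-year transitions
#'
#' Scans a person-year panel for pairs of consecutive-year records of the
#' same person and tabulates them by stratum (gender x age band), origin
#' state, destination state and period (pair of calendar years). The
#' stratum is assigned by gender and the age at the origin year of the
#' transition. A censored final observation (no next-year record and no
#' death record) contributes no transition; non-consecutive observations
#' (gaps) are censored, never imputed.
#'
#' @param panel a [person_year_panel()] spanning at least two years.
#' @return An object of class `transition_counts`: a 5-d array with
#'   dimensions `(gender = 2, age_group = 10, from = 7, to = 7, period)`,
#'   with period labels `"2004-2005"` etc.
#' @export
count_transitions <- function(panel) {
  yrs <- panel_years(panel)
  if (length(yrs) < 2L) stop("no transitions observable: panel has a single year")
  d <- as.data.frame(panel)
  d <- d[order(d$person_id, d$year), , drop = FALSE]
  n <- nrow(d)
  pair <- d$person_id[-1L] == d$person_id[-n] & d$year[-1L] - d$year[-n] == 1L
  io <- which(pair)             # origin rows of observed transitions
  if (!length(io)) stop("no transitions observable in panel")
  from <- d$state[io]
  if (any(from == "DEAD")) stop("transition out of DEAD state in panel")
  # periods are pairs of consecutive calendar years both present in the panel
  origins <- yrs[-length(yrs)][diff(yrs) == 1L]
  periods <- paste(origins, origins + 1L, sep = "-")
  counts <- table(
    gender = factor(d$gender[io], levels = genders()),
    age_group = factor(age_group_labels()[age_to_group(d$age[io])],
                       levels = age_group_labels()),
    from = factor(from, levels = health_states()),
    to = factor(d$state[io + 1L], levels = health_states()),
    period = factor(paste(d$year[io], d$year[io] + 1L, sep = "-"),
                    levels = periods))
  counts <- unclass(counts)
  storage.mode(counts) <- "integer"
  structure(counts, class = "transition_counts")
}

#' Row totals of a count array
#'
#' @param counts a `transition_counts`.
#' @return Array `(gender, age_group, from, period)` of origin-row totals
#'   \eqn{n_i(t-1)}.
#' @export
transition_row_totals <- function(counts) {
  apply(unclass(counts), c(1, 2, 3, 5), sum)
}

# normalize one (from x to) count matrix into a stochastic matrix with the
# identity fallback for unobserved origin rows; returns list(P, n_fallback)
normalize_counts <- function(nc) {
  m <- nrow(nc)
  P <- matrix(0, m, m, dimnames = dimnames(nc))
  totals <- rowSums(nc)
  fallback <- 0L
  for (i in seq_len(m)) {
    if (totals[i] > 0) {
      P[i, ] <- nc[i, ] / totals[i]
    } else {
      P[i, i] <- 1          # least-informative fallback: stay in state
      fallback <- fallback + 1L
    }
  }
  list(P = P, n_fallback = fallback)
}

#' Maximum-likelihood transition matrices
#'
#' Pools the transition counts over all observed periods and estimates each
#' transition probability as the simple frequency
#' \eqn{\hat p_{ij} = \sum_t n_{ij}(t) / \sum_z \sum_t n_{iz}(t)}.
#' Origin rows never observed in a stratum receive an identity fallback row
#' (stay in state), reported in a consolidated warning; the `DEAD` row is
#' always forced absorbing.
#'
#' @param counts a `transition_counts` from [count_transitions()].
#' @return A [transition_matrix_set()] with provenance `"pooled"`.
#' @export
estimate_matrices <- function(counts) {
  nc <- unclass(counts)
  pooled <- apply(nc, 1:4, sum)
  p <- array(0, dim = c(2L, 10L, n_states(), n_states()))
  n_fallback <- 0L
  for (g in 1:2) for (a in 1:10) {
    res <- normalize_counts(pooled[g, a, , ])
    res$P["DEAD", ] <- c(rep(0, n_states() - 1L), 1)
    p[g, a, , ] <- res$P
    n_fallback <- n_fallback + res$n_fallback
  }
  # the DEAD origin row is structurally unobserved everywhere (20 rows)
  n_fallback <- n_fallback - 20L
  if (n_fallback > 0L) {
    warning(sprintf(
      "%d unobserved origin row(s) received the identity fallback",
      n_fallback))
  }
  transition_matrix_set(p, provenance = "pooled")
}

#' Per-period transition matrices
#'
#' As [estimate_matrices()] but without pooling over periods: one matrix
#' set per pair of consecutive years, used by the stationarity test.
#'
#' @inheritParams estimate_matrices
#' @return Named list of [transition_matrix_set()], one per period.
#' @export
estimate_matrices_per_period <- function(counts) {
  nc <- unclass(counts)
  periods <- dimnames(nc)$period
  out <- vector("list", length(periods))
  names(out) <- periods
  for (t in seq_along(periods)) {
    p <- array(0, dim = c(2L, 10L, n_states(), n_states()))
    for (g in 1:2) for (a in 1:10) {
      res <- normalize_counts(nc[g, a, , , t])
      res$P["DEAD", ] <- c(rep(0, n_states() - 1L), 1)
      p[g, a, , ] <- res$P
    }
    out[[t]] <- suppressWarnings(
      transition_matrix_set(p, provenance = sprintf("period %s", periods[t])))
  }
  out
}

#' Chi-squared stationarity statistic for one chain
#'
#' Computes the homogeneity (stationarity) statistic
#' \eqn{\sum_t \sum_{i,j} n_i(t-1) (\hat p_{ij}(t) - \hat p_{ij})^2 /
#' \hat p_{ij}} comparing per-period transition frequencies to the pooled
#' estimate. Cells with pooled \eqn{\hat p_{ij} = 0} are skipped (0/0
#' convention) and reduce the adjusted degrees of freedom.
#'
#' Two degree-of-freedom conventions are reported: `df_nominal =
#' m(m-1) * P` (the textbook formula with `T` read as the number of
#' observation years, so `T-1 = P` period matrices), and `df_adjusted =
#' (free parameters) * (P-1)`, the classical convention for comparing `P`
#' estimated matrices to their own pool, with structurally-zero cells
#' removed from the free-parameter count. The p-value and the decision use
#' `df_adjusted`, which is the convention under which the statistic is
#' asymptotically chi-squared.
#'
#' @param nc integer array `(from = m, to = m, period = P)` of transition
#'   counts, `P >= 2`.
#' @param alpha significance level for the stationarity decision.
#' @return List with `statistic`, `df_nominal`, `df_adjusted`, `p_value`
#'   and `stationary`.
#' @export
stationarity_statistic <- function(nc, alpha = 0.05) {
  stopifnot(length(dim(nc)) == 3L, dim(nc)[1L] == dim(nc)[2L])
  m <- dim(nc)[1L]; P <- dim(nc)[3L]
  if (P < 2L) stop("stationarity test needs at least two periods")
  pooled_n <- apply(nc, c(1, 2), sum)
  pooled_tot <- rowSums(pooled_n)
  phat <- pooled_n / ifelse(pooled_tot > 0, pooled_tot, 1)
  stat <- 0
  for (t in seq_len(P)) {
    tot_t <- rowSums(nc[, , t])
    for (i in seq_len(m)) {
      if (tot_t[i] == 0) next
      pt <- nc[i, , t] / tot_t[i]
      ok <- phat[i, ] > 0
      stat <- stat + tot_t[i] * sum((pt[ok] - phat[i, ok])^2 / phat[i, ok])
    }
  }
  # free parameters: m-1 per observed row, minus structurally-zero cells
  free <- sum(vapply(seq_len(m), function(i) {
    max(0L, (m - 1L) - sum(phat[i, ] == 0))
  }, integer(1)))
  df_nominal <- m * (m - 1L) * P
  df_adjusted <- free * (P - 1L)
  p_value <- if (df_adjusted > 0) {
    stats::pchisq(stat, df = df_adjusted, lower.tail = FALSE)
  } else NA_real_
  list(statistic = stat, df_nominal = df_nominal, df_adjusted = df_adjusted,
       p_value = p_value,
       stationary = is.na(p_value) || p_value >= alpha)
}

#' Stationarity test per stratum
#'
#' Runs [stationarity_statistic()] on each of the 20 (gender, age band)
#' strata of a count array. The test informs, it never blocks: pooled
#' matrices remain usable for strata that fail.
#'
#' @param counts a `transition_counts` spanning at least two periods.
#' @param alpha significance level (default 0.05).
#' @return A data.frame of class `stationarity_result` with one row per
#'   stratum: `gender`, `age_group`, `statistic`, `df_nominal`,
#'   `df_adjusted`, `p_value`, `stationary`.
#' @export
stationarity_test <- function(counts, alpha = 0.05) {
  nc <- unclass(counts)
  if (dim(nc)[5L] < 2L) {
    stop("stationarity test needs at least two periods of counts")
  }
  rows <- list()
  for (g in 1:2) for (a in 1:10) {
    res <- stationarity_statistic(nc[g, a, , , ], alpha = alpha)
    rows[[length(rows) + 1L]] <- data.frame(
      gender = genders()[g], age_group = age_group_labels()[a],
      statistic = res$statistic, df_nominal = res$df_nominal,
      df_adjusted = res$df_adjusted, p_value = res$p_value,
      stationary = res$stationary, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("stationarity_result", "data.frame"),
            alpha = alpha)
}

#' Write a stationarity report to CSV
#'
#' @param result a `stationarity_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stationarity_report <- function(result, path) {
  utils::write.csv(as.data.frame(result), path, row.names = FALSE)
  invisible(path)
}

#' Estimate the cost table from a panel
#'
#' Cell means are arithmetic means of the annual cost over the person-year
#' records in the cell. The (gender, state) aggregate means are always
#' produced; with `by_age = TRUE`, (gender, age band, state) refinements
#' are added for cells with at least `min_cell` person-years, the rest
#' falling back to the aggregate at lookup time.
#'
#' @param panel a [person_year_panel()] with a `cost` column.
#' @param by_age add age-band-refined cells?
#' @param min_cell minimum person-years for an age-refined cell.
#' @return A [cost_table()].
#' @export
estimate_cost_table <- function(panel, by_age = FALSE, min_cell = 30L) {
  if (!"cost" %in% names(panel)) stop("panel has no cost column")
  d <- as.data.frame(panel)
  d <- d[d$state != "DEAD" & !is.na(d$cost), , drop = FALSE]
  if (!nrow(d)) stop("panel has no costed person-years")
  agg <- stats::aggregate(cost ~ gender + state, data = d, FUN = mean)
  names(agg)[names(agg) == "cost"] <- "mean_cost"
  agg$age_group <- NA_character_
  # unobserved (gender, state) aggregate cells fall back to the state mean
  need <- expand.grid(gender = genders(), state = transient_states(),
                      stringsAsFactors = FALSE)
  missing <- !paste(need$gender, need$state) %in% paste(agg$gender, agg$state)
  if (any(missing)) {
    st_mean <- stats::aggregate(cost ~ state, data = d, FUN = mean)
    overall <- mean(d$cost)
    fill <- need[missing, , drop = FALSE]
    fill$mean_cost <- st_mean$cost[match(fill$state, st_mean$state)]
    fill$mean_cost[is.na(fill$mean_cost)] <- overall
    fill$age_group <- NA_character_
    agg <- rbind(agg, fill)
  }
  out <- agg[, c("gender", "age_group", "state", "mean_cost")]
  if (by_age) {
    d$age_group <- age_group_labels()[age_to_group(d$age)]
    ref <- stats::aggregate(cost ~ gender + age_group + state, data = d,
                            FUN = mean)
    cnt <- stats::aggregate(cost ~ gender + age_group + state, data = d,
                            FUN = length)
    keep <- cnt$cost >= min_cell
    ref <- ref[keep, , drop = FALSE]
    names(ref)[names(ref) == "cost"] <- "mean_cost"
    out <- rbind(out, ref[, c("gender", "age_group", "state", "mean_cost")])
  }
  cost_table(out)
}
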