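#' Construct a cost table
#'
#' Mean annual healthcare cost in euros per (gender, health state) cell,
#' optionally refined by age band. A (gender, state) aggregate entry must
#' exist for every transient state so that age-refined lookups always have
#' a fallback.
#'
#' @param d data.frame with columns `gender`, `state`, `mean_cost`, and
#'   optionally `age_group` (band label, `NA` for the aggregate rows).
#' @return An object of class `cost_table` (a data.frame).
#' @export
cost_table <- function(d) {
  required <- c("gender", "state", "mean_cost")
  if (!all(required %in% names(d))) {
    stop("cost table needs columns ", paste(required, collapse = ", "))
  }
  d <- as.data.frame(d, stringsAsFactors = FALSE)
  gender_index(d$gender)
  state_index(d$state)
  if (any(d$state == "DEAD")) stop("no cost is attached to the DEAD state")
  if (any(is.na(d$mean_cost)) || any(d$mean_cost < 0)) {
    stop("mean costs must be non-negative")
  }
  if (!"age_group" %in% names(d)) d$age_group <- NA_character_
  agg <- d[is.na(d$age_group), , drop = FALSE]
  need <- expand.grid(gender = genders(), state = transient_states(),
                      stringsAsFactors = FALSE)
  have <- paste(agg$gender, agg$state)
  if (!all(paste(need$gender, need$state) %in% have)) {
    stop("cost table must have a (gender, state) aggregate entry for every transient state")
  }
  structure(d, class = c("cost_table", "data.frame"))
}

#' Build a cost table from a gender-by-state matrix of means
#'
#' @param means 2x6 matrix of mean annual costs (rows `F`, `M`; columns the
#'   transient states in fixed order).
#' @return A `cost_table` without age refinement.
#' @export
cost_table_from_means <- function(means) {
  stopifnot(is.matrix(means), all(dim(means) == c(2L, 6L)))
  cost_table(data.frame(
    gender = rep(genders(), each = 6L),
    state = rep(transient_states(), times = 2L),
    mean_cost = as.vector(t(means)),
    stringsAsFactors = FALSE))
}

#' Reference mean annual costs by gender and health state
#'
#' The default calibration of the synthetic generator: mean 2007-euro annual
#' healthcare costs by gender and aggregated CRG status on the scale
#' observed in a county-level integrated-care population, covering primary
#' care, specialised care, acute hospitalisation, long-term residential
#' care and out-of-institution pharmacy.
#'
#' @return 2x6 matrix (rows `F`, `M`) of euro means in the fixed state order.
#' @export
reference_cost_means <- function() {
  m <- rbind(
    F = c(324.16, 1692.67, 1069.41, 2739.67, 11095.93, 5617.47),
    M = c(227.42, 1195.57,  936.65, 2334.04, 10113.71, 5519.98))
  colnames(m) <- transient_states()
  m
}

#' Look up mean costs
#'
#' Vectorized lookup of the mean annual cost for (gender, age band, state)
#' triples. If the table carries age-refined rows, the refined cell is used
#' when present and the (gender, state) aggregate otherwise; without age
#' refinement the aggregate is always used. `DEAD` states cost 0.
#'
#' @param ct a `cost_table`.
#' @param gender character vector of `"F"`/`"M"`.
#' @param band integer vector of age-band indices (1..10).
#' @param state character vector of state labels.
#' @return Numeric vector of euro means.
#' @export
cost_lookup <- function(ct, gender, band, state) {
  n <- max(length(gender), length(band), length(state))
  gender <- rep_len(gender, n); band <- rep_len(band, n)
  state <- rep_len(state, n)
  out <- numeric(n)
  dead <- state == "DEAD"
  agg <- ct[is.na(ct$age_group), , drop = FALSE]
  key_agg <- paste(agg$gender, agg$state)
  out[!dead] <- agg$mean_cost[match(paste(gender, state)[!dead], key_agg)]
  ref <- ct[!is.na(ct$age_group), , drop = FALSE]
  if (nrow(ref) && any(!dead)) {
    key_ref <- paste(ref$gender, ref$age_group, ref$state)
    hit <- match(paste(gender, age_group_labels()[band], state), key_ref)
    use <- !dead & !is.na(hit)
    out[use] <- ref$mean_cost[hit[use]]
  }
  if (anyNA(out)) stop("cost table has no entry for a requested (gender, state)")
  out
}

#' Write / read a cost table as CSV
#'
#' Columns `gender, age_group, state, mean_cost`; `age_group` is empty for
#' the (gender, state) aggregate rows.
#'
#' @param ct a `cost_table`.
#' @param path file path.
#' @return `path` (write) or a `cost_table` (read).
#' @export
write_cost_table <- function(ct, path) {
  out <- as.data.frame(ct)[, c("gender", "age_group", "state", "mean_cost")]
  out$mean_cost <- sprintf("%.6f", out$mean_cost)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cost_table
#' @export
read_cost_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  cost_table(d)
}
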