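# toy fixtures shared across tests; everything is built in code

# a 3-person, 2-year panel: A stays healthy, B has an acute episode,
# C (an 80-year-old man) dies
toy_panel_records <- function() {
  data.frame(
    person_id = c("A", "A", "B", "B", "C", "C"),
    year = c(2004L, 2005L, 2004L, 2005L, 2004L, 2005L),
    gender = c("F", "F", "F", "F", "M", "M"),
    age = c(30L, 31L, 40L, 41L, 80L, 81L),
    state = c("E1", "E1", "E1", "E2", "E56", "DEAD"),
    stringsAsFactors = FALSE)
}

# 7x7 matrix: one transient state (E1) with constant death probability q;
# all other transient states die immediately
single_state_matrix <- function(q) {
  P <- matrix(0, 7, 7, dimnames = list(health_states(), health_states()))
  P[1, 1] <- 1 - q
  P[1, 7] <- q
  for (i in 2:6) P[i, 7] <- 1
  P[7, 7] <- 1
  P
}

# embed a k x k substochastic transient block Q (k <= 6) into a 7x7
# absorbing-chain matrix; remaining transient states die immediately
absorbing_matrix <- function(Q) {
  k <- nrow(Q)
  stopifnot(k <= 6, all(rowSums(Q) <= 1 + 1e-12))
  P <- matrix(0, 7, 7, dimnames = list(health_states(), health_states()))
  P[1:k, 1:k] <- Q
  P[1:k, 7] <- 1 - rowSums(Q)
  if (k < 6) for (i in (k + 1):6) P[i, 7] <- 1
  P[7, 7] <- 1
  P
}

# initial mix with all mass on one or more states, split across genders
mix_on <- function(states, shares = NULL, gender_split = c(0.5, 0.5)) {
  m <- matrix(0, 2, 6, dimnames = list(genders(), transient_states()))
  if (is.null(shares)) shares <- rep(1 / length(states), length(states))
  for (g in 1:2) m[g, states] <- gender_split[g] * shares
  initial_mix(m)
}

# random substochastic transient block with guaranteed extinction
random_transient_block <- function(k, min_death = 0.02) {
  w <- matrix(stats::runif(k * k), k, k)
  w <- w / rowSums(w) * (1 - stats::runif(k, min_death, 0.3))
  w
}
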