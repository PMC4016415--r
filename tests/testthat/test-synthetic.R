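test_that("ground-truth matrices are stochastic with an absorbing death state", {
  truth <- make_ground_truth(synth_config())
  p <- unclass(truth$matrices)
  rs <- apply(p, c(1, 2, 3), sum)
  expect_lt(max(abs(rs - 1)), 1e-12)
  expect_true(all(p >= 0))
  expect_true(all(p[, , 7, 7] == 1))
  expect_identical(sum(truth$initial_mix), 1)
  expect_gt(sum(truth$initial_mix[, "E1"]), 0.9)
})

test_that("mortality is non-decreasing across age bands in every stratum", {
  truth <- make_ground_truth(synth_config())
  p <- unclass(truth$matrices)
  for (g in 1:2) for (s in 1:6) {
    expect_true(all(diff(p[g, , s, 7]) >= -1e-15),
                info = sprintf("gender %d state %d", g, s))
  }
  # the stated example: death from E56 at 85+ exceeds death at 45-54
  expect_gt(p[1, 10, 4, 7], p[1, 6, 4, 7])
})

test_that("women of childbearing age have elevated acute-episode risk", {
  truth <- make_ground_truth(synth_config())
  p <- unclass(truth$matrices)
  for (band in 3:5) {
    expect_gt(p[1, band, 1, 2], p[2, band, 1, 2])
  }
  # outside those bands the generator applies no female acute excess
  expect_lt(abs(p[1, 7, 1, 2] / p[2, 7, 1, 2] - 1), 0.2)
})

test_that("forward-simulated healthy prevalence lies in the target band", {
  truth <- make_ground_truth(synth_config())
  occ <- run_cohort(truth$matrices, initial_mix(truth$initial_mix),
                    size = 1e5)
  alive <- sum(occ$mass[, , 1:6])
  prev <- sum(occ$mass[, , 1]) / alive
  expect_gt(prev, 0.55)
  expect_lt(prev, 0.75)
})

test_that("invalid generator configurations are rejected", {
  expect_error(synth_config(severity_gradient = 0), "positive")
  expect_error(synth_config(n_individuals = 0), ">= 1")
  expect_error(synth_config(years = 2004L), "two consecutive")
  expect_error(synth_config(migration_out_rate = 1), "migration")
})

test_that("identity dynamics freeze every individual in its initial state", {
  cfg <- synth_config(n_individuals = 500, years = 2004:2007, seed = 7,
                      migration_out_rate = 0, migration_in_rate = 0)
  truth <- make_ground_truth(cfg)
  truth$matrices <- homogeneous_matrix_set(diag(7))
  panel <- generate_panel(truth, cfg)
  per_person <- tapply(panel$state, panel$person_id,
                       function(s) length(unique(s)))
  expect_true(all(per_person == 1L))
  expect_false(any(panel$state == "DEAD"))
  expect_identical(nrow(panel), 500L * 4L)
})

test_that("the generator is deterministic in its seed and passes validation", {
  cfg <- synth_config(n_individuals = 800, years = 2004:2006, seed = 11)
  truth <- make_ground_truth(cfg)
  p1 <- generate_panel(truth, cfg)
  p2 <- generate_panel(truth, cfg)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  # state paths are unchanged when cost generation is toggled off
  p3 <- generate_panel(truth, cfg, costs = FALSE)
  expect_identical(p1$state, p3$state)
  expect_false("cost" %in% names(p3))
  # a generated panel always passes validation with no fatal issue
  report <- validate_panel(as.data.frame(p1))
  expect_false(any(report$severity == "error"))
})

test_that("censored individuals stop without a death record", {
  cfg <- synth_config(n_individuals = 2000, years = 2004:2007, seed = 3,
                      migration_out_rate = 0.3, migration_in_rate = 0)
  truth <- make_ground_truth(cfg)
  panel <- generate_panel(truth, cfg)
  last <- tapply(seq_len(nrow(panel)), panel$person_id, max)
  last_state <- panel$state[last]
  last_year <- panel$year[last]
  censored <- last_year < max(cfg$years) & last_state != "DEAD"
  expect_gt(sum(censored), 0)
  # no person has any record after a DEAD record (terminal death)
  expect_false(any(unlist(tapply(panel$state, panel$person_id,
                                 function(s) which(s == "DEAD") < length(s)))))
})

test_that("annual cost draws have the configured mean and right skew", {
  model <- list(means = reference_cost_means(), cv = 1.5)
  expect_error(sample_annual_cost("F", "DEAD", model), "DEAD")
  # zero dispersion degenerates to the exact mean
  d0 <- sample_annual_cost(rep("M", 10), "E34",
                           list(means = reference_cost_means(), cv = 0))
  expect_identical(d0, rep(936.65, 10))
  set.seed(42)
  x <- sample_annual_cost(rep("F", 1e5), "E79", model)
  expect_gt(mean(x), 11095.93 * 0.99)
  expect_lt(mean(x), 11095.93 * 1.01)
  expect_gt(mean((x - mean(x))^3), 0)   # right-skewed
  expect_true(all(x >= 0))
})

test_that("transition frequencies in a large panel recover the truth", {
  cfg <- synth_config(n_individuals = 5000, years = 2004:2007, seed = 5)
  truth <- make_ground_truth(cfg)
  panel <- generate_panel(truth, cfg)
  counts <- count_transitions(panel)
  est <- suppressWarnings(estimate_matrices(counts))
  pooled <- apply(unclass(counts), 1:4, sum)
  totals <- apply(pooled, c(1, 2, 3), sum)
  idx <- which(totals >= 50, arr.ind = TRUE)
  idx <- idx[idx[, 3] != 7, , drop = FALSE]     # transient origins only
  inside <- 0L; n_cells <- 0L
  for (r in seq_len(nrow(idx))) {
    g <- idx[r, 1]; a <- idx[r, 2]; i <- idx[r, 3]
    n_i <- totals[g, a, i]
    for (j in 1:7) {
      p0 <- unclass(truth$matrices)[g, a, i, j]
      se <- sqrt(p0 * (1 - p0) / n_i)
      n_cells <- n_cells + 1L
      if (abs(est[g, a, i, j] - p0) <= 3 * se) inside <- inside + 1L
    }
  }
  expect_gt(inside / n_cells, 0.95)
})
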