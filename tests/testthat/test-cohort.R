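test_that("a single-state chain reproduces the geometric closed form", {
  ms <- homogeneous_matrix_set(single_state_matrix(0.1))
  mix <- mix_on("E1")
  occ <- run_cohort(ms, mix, size = 1e5, max_age = 400L,
                    extinction_tol = 1e-12)
  ey <- expected_years(occ)
  expect_equal(ey["F", "E1"], 10, tolerance = 1e-9)
  expect_equal(ey["M", "E1"], 10, tolerance = 1e-9)
  expect_identical(sum(ey[, 2:6]), 0)
  # survivors decay geometrically: mass at age a is size * 0.9^a
  expect_equal(occ$mass[11, "F", "E1"], 5e4 * 0.9^10, tolerance = 1e-6)
  ct <- cost_table_from_means(matrix(500, 2, 6))
  expect_equal(unname(lifetime_mean_cost(occ, ct)), c(5000, 5000),
               tolerance = 1e-8)
})

test_that("expected years match the fundamental matrix on homogeneous chains", {
  set.seed(20)
  for (k in 2:6) {
    Q <- random_transient_block(k)
    occ <- run_cohort(homogeneous_matrix_set(absorbing_matrix(Q)),
                      mix_on(1:k), size = 1e5, max_age = 600L,
                      extinction_tol = 1e-12)
    ey <- expected_years(occ)
    start <- rep(1 / k, k)
    oracle <- solve(diag(k) - t(Q), start)   # start' (I-Q)^{-1}
    expect_equal(unname(ey["F", 1:k]), unname(oracle), tolerance = 1e-6)
    expect_equal(unname(ey["M", 1:k]), unname(oracle), tolerance = 1e-6)
  }
})

test_that("mass is conserved and death is monotone at every age", {
  truth <- make_ground_truth(synth_config())
  occ <- run_cohort(truth$matrices, initial_mix(truth$initial_mix),
                    size = 1e5)
  per_age <- apply(occ$mass, c(1, 2), sum)
  for (g in 1:2) {
    expect_lt(max(abs(per_age[, g] - occ$initial[g])), 1e-6 * occ$size)
    expect_true(all(diff(occ$mass[, g, 7]) >= -1e-9))
    alive <- rowSums(occ$mass[, g, 1:6])
    expect_true(all(diff(alive) <= 1e-9))
  }
  # the cohort ends extinct
  expect_lt(sum(occ$mass[length(occ$ages), , 1:6]), 1e-6 * occ$size)
})

test_that("immediate death yields exactly one start-of-year person-year", {
  P <- single_state_matrix(1)
  occ <- run_cohort(homogeneous_matrix_set(P), mix_on("E1"), size = 1000)
  ey <- expected_years(occ)
  expect_equal(unname(ey[, "E1"]), c(1, 1))
  expect_identical(sum(ey[, 2:6]), 0)
})

test_that("per-gender life expectancy decomposes over states", {
  truth <- make_ground_truth(synth_config())
  occ <- run_cohort(truth$matrices, initial_mix(truth$initial_mix),
                    size = 1e5)
  res <- cohort_result(occ)
  for (g in genders()) {
    agg <- aggregate_expectancy(res$expected_years[g, ])
    expect_equal(agg$total, res$total_le[[g]], tolerance = 1e-9)
    expect_equal(agg$total,
                 agg$healthy_years + agg$chronic_years +
                   res$expected_years[g, "E2"],
                 tolerance = 1e-9)
  }
})

test_that("yearly mean cost is survivor-weighted and missing after extinction", {
  truth <- make_ground_truth(synth_config())
  occ <- run_cohort(truth$matrices, initial_mix(truth$initial_mix),
                    size = 1e5)
  # uniform costs collapse to the constant at every age with survivors
  flat <- cost_table_from_means(matrix(777, 2, 6))
  yc <- yearly_mean_cost(occ, flat)
  alive_ages <- rowSums(occ$mass[, 1, 1:6]) > 0
  expect_equal(yc$mean_cost[yc$gender == "F"][alive_ages],
               rep(777, sum(alive_ages)), tolerance = 1e-9)
  expect_true(all(is.na(yc$mean_cost[yc$gender == "F"][!alive_ages])))

  # all mass healthy: the female curve sits at the healthy female mean
  occ1 <- run_cohort(homogeneous_matrix_set(single_state_matrix(0.05)),
                     mix_on("E1"), size = 1e4)
  yc1 <- yearly_mean_cost(occ1, cost_table_from_means(reference_cost_means()))
  f <- yc1[yc1$gender == "F" & !is.na(yc1$mean_cost), ]
  expect_equal(unique(round(f$mean_cost, 10)), 324.16)
})

test_that("lifetime cost equals the expectancy-cost inner product", {
  truth <- make_ground_truth(synth_config())
  occ <- run_cohort(truth$matrices, initial_mix(truth$initial_mix),
                    size = 1e5)
  ct <- cost_table_from_means(truth$cost_model$means)
  lc <- lifetime_mean_cost(occ, ct)
  ey <- expected_years(occ)
  for (g in genders()) {
    expect_equal(lc[[g]],
                 sum(ey[g, ] * truth$cost_model$means[g, ]),
                 tolerance = 1e-9)
  }
  zero <- cost_table_from_means(matrix(0, 2, 6))
  expect_equal(unname(lifetime_mean_cost(occ, zero)), c(0, 0))
})

test_that("non-stochastic inputs are rejected before iteration", {
  bad <- single_state_matrix(0.1)
  bad[1, 1] <- 0.95    # row sums to 1.05
  expect_error(homogeneous_matrix_set(bad), "non-stochastic")
  truth <- make_ground_truth(synth_config())
  expect_error(run_cohort(truth$matrices, initial_mix(truth$initial_mix),
                          size = -1), "positive")
})
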