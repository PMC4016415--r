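test_that("transition counting matches a hand count of the toy panel", {
  panel <- person_year_panel(toy_panel_records())
  counts <- count_transitions(panel)
  nc <- unclass(counts)
  expect_identical(dim(nc), c(2L, 10L, 7L, 7L, 1L))
  # A: female, 30 -> band 25-34, E1 -> E1
  expect_identical(nc[1, 4, 1, 1, 1], 1L)
  # B: female, 40 -> band 35-44, E1 -> E2
  expect_identical(nc[1, 5, 1, 2, 1], 1L)
  # C: male, 80 -> band 75-84, E56 -> DEAD
  expect_identical(nc[2, 9, 4, 7, 1], 1L)
  expect_identical(sum(nc), 3L)
})

test_that("singletons and gap years contribute no transitions", {
  rec <- toy_panel_records()
  # person D observed once; person E observed 2004 and 2006 (gap)
  rec <- rbind(rec, data.frame(person_id = c("D", "E", "E"),
                               year = c(2004L, 2004L, 2006L),
                               gender = "M", age = c(50L, 60L, 62L),
                               state = "E34", stringsAsFactors = FALSE))
  counts <- count_transitions(person_year_panel(rec))
  expect_identical(sum(unclass(counts)), 3L)     # only A, B, C count
  expect_identical(sum(unclass(counts)[, , 3, , ]), 0L)  # no E34 origin

  single <- person_year_panel(toy_panel_records()[c(1, 3), ])
  expect_error(count_transitions(single), "single year")
})

test_that("the pooled estimator is the printed count ratio", {
  rec <- do.call(rbind, lapply(1:10, function(i) {
    data.frame(person_id = sprintf("P%02d", i), year = c(2004L, 2005L),
               gender = "F", age = c(30L, 31L),
               state = c("E1", if (i <= 8) "E1" else "E2"),
               stringsAsFactors = FALSE)
  }))
  ms <- suppressWarnings(estimate_matrices(
    count_transitions(person_year_panel(rec))))
  expect_equal(ms[1, 4, 1, 1], 0.8)
  expect_equal(ms[1, 4, 1, 2], 0.2)
  expect_equal(sum(ms[1, 4, 1, ]), 1)
  # DEAD row is always the unit vector on DEAD
  expect_identical(ms[1, 4, 7, ], c(rep(0, 6), 1),
                   ignore_attr = TRUE)
  # unobserved origin rows fall back to the identity
  expect_identical(ms[2, 1, 3, 3], 1)
  expect_warning(estimate_matrices(
    count_transitions(person_year_panel(rec))), "fallback")
})

test_that("per-period estimates pool to the stationary estimate", {
  mk <- function(year0, n_move) {
    do.call(rbind, lapply(1:10, function(i) {
      data.frame(person_id = sprintf("Y%d_%02d", year0, i),
                 year = c(year0, year0 + 1L), gender = "M",
                 age = c(50L, 51L),
                 state = c("E1", if (i <= n_move) "E2" else "E1"),
                 stringsAsFactors = FALSE)
    }))
  }
  # two periods with 1/10 and 3/10 moves; persons observed in one period
  panel <- person_year_panel(rbind(mk(2004L, 1L), mk(2005L, 3L)))
  counts <- count_transitions(panel)
  per <- suppressWarnings(estimate_matrices_per_period(counts))
  expect_length(per, 2L)
  expect_equal(per[["2004-2005"]][2, 6, 1, 2], 0.1)
  expect_equal(per[["2005-2006"]][2, 6, 1, 2], 0.3)
  pooled <- suppressWarnings(estimate_matrices(counts))
  expect_equal(pooled[2, 6, 1, 2], 0.2)
  # pooled counts equal the sum of per-period counts
  expect_identical(apply(unclass(counts), 1:4, sum),
                   unclass(counts)[, , , , 1] + unclass(counts)[, , , , 2])
})

test_that("stationarity statistic matches the hand-computed example", {
  # 2-state chain: period rows (9,1) and (7,3) out of 10; pooled (0.8, 0.2)
  nc <- array(0L, dim = c(2, 2, 2))
  nc[1, , 1] <- c(9L, 1L)
  nc[1, , 2] <- c(7L, 3L)
  res <- stationarity_statistic(nc)
  expect_equal(res$statistic, 1.25)
  expect_identical(res$df_nominal, 2L * 1L * 2L)
  expect_identical(res$df_adjusted, 1L)   # one observed row, one extra period
  expect_true(res$stationary)
})

test_that("identical per-period frequencies give statistic zero", {
  nc <- array(0L, dim = c(3, 3, 2))
  for (t in 1:2) nc[, , t] <- matrix(c(8, 1, 1, 2, 6, 2, 1, 1, 8) * 10,
                                     3, 3, byrow = TRUE)
  res <- stationarity_statistic(nc)
  expect_equal(res$statistic, 0)
  expect_true(res$stationary)
  # nominal df follows m(m-1) x periods
  expect_identical(res$df_nominal, 3L * 2L * 2L)
  expect_identical(res$df_adjusted, 3L * 2L * 1L)
})

test_that("the stratified test runs per stratum and respects alpha", {
  cfg <- synth_config(n_individuals = 3000, years = 2004:2007, seed = 9)
  truth <- make_ground_truth(cfg)
  panel <- generate_panel(truth, cfg)
  counts <- count_transitions(panel)
  res <- stationarity_test(counts, alpha = 0.05)
  expect_s3_class(res, "stationarity_result")
  expect_identical(nrow(res), 20L)
  expect_true(all(res$statistic >= 0))
  expect_true(all(res$df_adjusted <= res$df_nominal))
  expect_identical(res$stationary,
                   is.na(res$p_value) | res$p_value >= 0.05)
  one_period <- count_transitions(
    person_year_panel(panel[panel$year <= 2005, ]))
  expect_error(stationarity_test(one_period), "two periods")
})

test_that("cost table estimation averages cells and falls back", {
  rec <- toy_panel_records()
  rec$cost <- c(100, 300, 50, 500, 70, 0)
  panel <- person_year_panel(rec)
  ct <- estimate_cost_table(panel)
  # female E1 person-years carry costs {100, 300, 50}
  expect_equal(cost_lookup(ct, "F", 4, "E1"), 150)
  expect_equal(cost_lookup(ct, "M", 9, "E56"), 70)
  # age refinement: cells meeting the person-year threshold are refined,
  # cells below it fall back to the (gender, state) aggregate
  ct2 <- estimate_cost_table(panel, by_age = TRUE, min_cell = 2)
  expect_equal(cost_lookup(ct2, "F", 4, "E1"), 200)   # {100, 300} refined
  expect_equal(cost_lookup(ct2, "F", 5, "E1"), 150)   # 1 record: aggregate
  no_cost <- person_year_panel(toy_panel_records())
  expect_error(estimate_cost_table(no_cost), "no cost column")
})

test_that("zero-dispersion costs are recovered exactly", {
  cfg <- synth_config(n_individuals = 2000, years = 2004:2006, seed = 13,
                      cost_cv = 0)
  truth <- make_ground_truth(cfg)
  panel <- generate_panel(truth, cfg)
  ct <- estimate_cost_table(panel)
  means <- reference_cost_means()
  for (g in genders()) for (s in transient_states()) {
    observed <- any(panel$gender == g & panel$state == s)
    if (observed) {
      expect_identical(cost_lookup(ct, g, 1, s), means[g, s],
                       label = sprintf("%s %s", g, s))
    }
  }
  expect_identical(cost_lookup(ct, "F", 1, "E56"), 2739.67)
})
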