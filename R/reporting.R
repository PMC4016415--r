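#' Aggregate per-state expected years into headline measures
#'
#' @param years named numeric vector with one value per transient state
#'   (names `E1`, `E2`, `E34`, `E56`, `E79`, `E8`).
#' @return List with `total` (sum of all six), `chronic_years` (sum over
#'   the chronic subset `E34`, `E56`, `E79`, `E8`) and `healthy_years`
#'   (the `E1` value), at full precision.
#' @examples
#' aggregate_expectancy(c(E1 = 46.99, E2 = 8.39, E34 = 7.74, E56 = 19.96,
#'                        E79 = 0.52, E8 = 0.19))
#' @export
aggregate_expectancy <- function(years) {
  missing_states <- setdiff(transient_states(), names(years))
  if (length(missing_states)) {
    stop("missing state value(s): ", paste(missing_states, collapse = ", "))
  }
  years <- years[transient_states()]
  if (anyNA(years)) stop("expected years contain NA")
  list(total = sum(years),
       chronic_years = sum(years[chronic_states()]),
       healthy_years = unname(years["E1"]))
}

#' Relative difference between the two projection engines
#'
#' The Monte-Carlo microsimulation is biased only by pseudo-random
#' sampling; its distance to the exact cohort value is the natural check
#' of agreement between the two strategies.
#'
#' @param cohort_value exact cohort-engine value (> 0).
#' @param mc_value Monte-Carlo estimate of the same quantity (> 0).
#' @return `100 * |cohort_value - mc_value| / cohort_value`, in percent.
#' @examples
#' compare_engines(111935.96, 111255.10)   # 0.608%
#' @export
compare_engines <- function(cohort_value, mc_value) {
  if (any(cohort_value <= 0) || any(mc_value <= 0)) {
    stop("engine comparison needs positive values")
  }
  100 * abs(cohort_value - mc_value) / cohort_value
}

#' Pipeline run configuration
#'
#' @param out_dir output directory (created if absent).
#' @param panel_path optional path to an existing panel CSV; if `NULL` a
#'   synthetic panel is generated from `synth`.
#' @param synth a [synth_config()] for the synthetic stage.
#' @param cohort_size initial cohort size (default 100,000).
#' @param n_per_gender Monte-Carlo pathways per gender (default 10,000).
#' @param max_age hard age cap (default 110).
#' @param seed seed for the Monte-Carlo stage.
#' @param alpha significance level of the stationarity test.
#' @param make_figures write convenience PNG figures?
#' @return Validated list of class `run_config`.
#' @export
run_config <- function(out_dir, panel_path = NULL, synth = synth_config(),
                       cohort_size = 1e5, n_per_gender = 10000L,
                       max_age = 110L, seed = 1L, alpha = 0.05,
                       make_figures = FALSE) {
  if (cohort_size <= 0 || n_per_gender <= 0 || max_age < 1) {
    stop("cohort_size, n_per_gender and max_age must be positive")
  }
  if (!is.null(panel_path) && !file.exists(panel_path)) {
    stop("panel file does not exist: ", panel_path)
  }
  structure(list(out_dir = out_dir, panel_path = panel_path, synth = synth,
                 cohort_size = cohort_size,
                 n_per_gender = as.integer(n_per_gender),
                 max_age = as.integer(max_age), seed = as.integer(seed),
                 alpha = alpha, make_figures = make_figures),
            class = "run_config")
}

pipeline_log <- function(con, level, msg) {
  line <- sprintf("%s [%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  level, msg)
  writeLines(line, con)
}

#' Run the whole projection pipeline
#'
#' Orchestrates synthesize (optional) -> count -> estimate -> stationarity
#' test -> cohort propagation -> Monte-Carlo microsimulation -> report,
#' writing every intermediate artifact to `config$out_dir`: the panel, the
#' pooled matrix set, the cost table, the stationarity report, the cohort
#' occupancy, expectancy and cost summaries (per-state years with the
#' Monte-Carlo mean/SD/min/max next to the exact cohort means), the
#' lifetime-cost distribution summary, the engine comparison, and a
#' timestamped log. Numeric outputs are deterministic given the seeds.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the in-memory stage results and the
#'   paths of the written artifacts.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(log = file.path(config$out_dir, "run.log"))
  con <- file(paths$log, open = "wt")
  on.exit(close(con), add = TRUE)
  step <- function(name, expr) {
    pipeline_log(con, "INFO", sprintf("stage %s: start", name))
    tryCatch(expr, error = function(e) {
      pipeline_log(con, "ERROR", sprintf("stage %s: %s", name, conditionMessage(e)))
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  truth <- NULL
  if (is.null(config$panel_path)) {
    panel <- step("synth", {
      truth <- make_ground_truth(config$synth)
      generate_panel(truth, config$synth)
    })
    paths$truth_matrices <- file.path(config$out_dir, "truth_matrices.csv")
    write_matrix_set(truth$matrices, paths$truth_matrices)
    paths$panel <- file.path(config$out_dir, "panel.csv")
    write_panel(panel, paths$panel)
    pipeline_log(con, "INFO", sprintf("synth: %d records (seed %d)",
                                      nrow(panel), config$synth$seed))
  } else {
    panel <- step("read", read_panel(config$panel_path))
    pipeline_log(con, "INFO", sprintf("read: %d records from %s",
                                      nrow(panel), config$panel_path))
  }

  counts <- step("count", count_transitions(panel))
  matrices <- step("estimate", withCallingHandlers(
    estimate_matrices(counts),
    warning = function(w) {
      pipeline_log(con, "WARN", conditionMessage(w))
      invokeRestart("muffleWarning")
    }))
  paths$matrices <- file.path(config$out_dir, "matrices.csv")
  write_matrix_set(matrices, paths$matrices)

  costs <- step("costs", estimate_cost_table(panel))
  paths$cost_table <- file.path(config$out_dir, "cost_table.csv")
  write_cost_table(costs, paths$cost_table)

  stat <- step("test-stationarity", stationarity_test(counts, config$alpha))
  paths$stationarity <- file.path(config$out_dir, "stationarity.csv")
  write_stationarity_report(stat, paths$stationarity)
  n_nonstat <- sum(!stat$stationary)
  if (n_nonstat > 0) {
    pipeline_log(con, "WARN", sprintf(
      "%d stratum(s) fail the stationarity test at alpha %.2f; pooled matrices used regardless",
      n_nonstat, config$alpha))
  }

  mix <- step("mix", initial_mix_from_panel(panel))
  occ <- step("cohort", run_cohort(matrices, mix, size = config$cohort_size,
                                   max_age = config$max_age))
  cres <- cohort_result(occ, costs)
  paths$occupancy <- file.path(config$out_dir, "occupancy.csv")
  write_occupancy(occ, paths$occupancy)

  mc <- step("mc", simulate_collection(matrices, mix,
                                       n_per_gender = config$n_per_gender,
                                       costs = costs, seed = config$seed,
                                       max_age = config$max_age))

  report <- step("report", {
    ysum <- summarize_years(mc)
    ysum$cohort_mean <- as.vector(t(cres$expected_years))[
      match(paste(ysum$gender, ysum$state),
            paste(rep(genders(), each = 6L), rep(transient_states(), 2L)))]
    csum <- rbind(summarize_costs(mc, "F"), summarize_costs(mc, "M"))
    mc_mean <- stats::setNames(csum$mean, csum$gender)[genders()]
    comp <- data.frame(
      gender = genders(),
      cohort_mean_cost = cres$lifetime_mean_cost,
      mc_mean_cost = mc_mean,
      rel_diff_pct = compare_engines(cres$lifetime_mean_cost, mc_mean),
      stringsAsFactors = FALSE)
    agg <- do.call(rbind, lapply(genders(), function(g) {
      a <- aggregate_expectancy(cres$expected_years[g, ])
      data.frame(gender = g, total_le = a$total,
                 healthy_years = a$healthy_years,
                 chronic_years = a$chronic_years, stringsAsFactors = FALSE)
    }))
    list(years = ysum, costs = csum, comparison = comp, aggregates = agg)
  })
  paths$expected_years <- file.path(config$out_dir, "expected_years.csv")
  utils::write.csv(report$years, paths$expected_years, row.names = FALSE)
  paths$cost_summary <- file.path(config$out_dir, "lifetime_cost_summary.csv")
  utils::write.csv(report$costs, paths$cost_summary, row.names = FALSE)
  paths$comparison <- file.path(config$out_dir, "engine_comparison.csv")
  utils::write.csv(report$comparison, paths$comparison, row.names = FALSE)
  paths$aggregates <- file.path(config$out_dir, "expectancy_aggregates.csv")
  utils::write.csv(report$aggregates, paths$aggregates, row.names = FALSE)
  paths$yearly_cost <- file.path(config$out_dir, "yearly_mean_cost.csv")
  utils::write.csv(cres$yearly_mean_cost, paths$yearly_cost, row.names = FALSE)

  if (isTRUE(config$make_figures)) {
    step("figures", pipeline_figures(cres, mc, config$out_dir))
    paths$figures <- file.path(config$out_dir,
                               c("occupancy_F.png", "occupancy_M.png",
                                 "yearly_cost.png", "lifetime_cost_hist.png"))
  }
  pipeline_log(con, "INFO", "pipeline complete")
  invisible(list(panel = panel, truth = truth, counts = counts,
                 matrices = matrices, costs = costs, stationarity = stat,
                 cohort = cres, mc = mc, report = report, paths = paths))
}

# convenience figures: occupancy areas per gender, yearly cost curves,
# lifetime-cost histograms
pipeline_figures <- function(cres, mc, out_dir) {
  occ <- cres$occupancy
  shades <- grDevices::grey.colors(n_states(), start = 0.95, end = 0.2)
  for (g in 1:2) {
    grDevices::png(file.path(out_dir, sprintf("occupancy_%s.png", genders()[g])),
                   width = 800, height = 500)
    share <- occ$mass[, g, ] / rowSums(occ$mass[, g, ])
    cum <- t(apply(share, 1, cumsum))
    graphics::plot(NULL, xlim = range(occ$ages), ylim = c(0, 1),
                   xlab = "age", ylab = "probability",
                   main = sprintf("State occupancy by age (%s)", genders()[g]))
    for (s in rev(seq_len(n_states()))) {
      graphics::polygon(c(occ$ages, rev(occ$ages)),
                        c(cum[, s], rep(0, length(occ$ages))),
                        col = shades[s], border = NA)
    }
    graphics::legend("left", legend = health_states(), fill = shades, cex = 0.8)
    grDevices::dev.off()
  }
  yc <- cres$yearly_mean_cost
  grDevices::png(file.path(out_dir, "yearly_cost.png"), width = 800, height = 500)
  graphics::plot(yc$age[yc$gender == "F"], yc$mean_cost[yc$gender == "F"],
                 type = "l", xlab = "age", ylab = "mean cost (euros)",
                 main = "Yearly mean cost per survivor")
  graphics::lines(yc$age[yc$gender == "M"], yc$mean_cost[yc$gender == "M"],
                  lty = 2)
  graphics::legend("topleft", legend = c("F", "M"), lty = 1:2)
  grDevices::dev.off()
  grDevices::png(file.path(out_dir, "lifetime_cost_hist.png"),
                 width = 800, height = 500)
  graphics::par(mfrow = c(1, 2))
  for (g in genders()) {
    graphics::hist(mc$lifetime_cost[mc$gender == g], breaks = 40,
                   main = sprintf("Lifetime cost (%s)", g),
                   xlab = "euros", col = "grey80", border = "white")
  }
  grDevices::dev.off()
  invisible(NULL)
}
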