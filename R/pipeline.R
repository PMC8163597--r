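# End-to-end orchestration: read or simulate observations, assemble
# restorations, score consistency and difficulty, stratify, run the
# statistical comparisons, and (optionally) write a report bundle.

#' Run the full analysis pipeline
#'
#' Executes read/simulate -> assemble -> consistency -> difficulty ->
#' stratification -> comparisons on one dataset and returns all intermediate
#' and final products, together with a log of counts at every stage. When
#' `out_dir` is given, also writes `observations.csv` (simulated input only),
#' `summaries.csv`, `difficulty.csv`, `table_groups.csv` (the stratified
#' descriptives), `table_years.csv` (per-year consistency and volumes),
#' `tests.json` and `run.log`. Outputs are deterministic: re-running with the
#' same input or simulation seed reproduces them byte for byte.
#'
#' The Kolmogorov-Smirnov cohort check is run (when exactly two cohorts are
#' present) on two per-student quantities: total restoration count and
#' overall pooled consistency. The ANOVA compares per-student yearly
#' consistency across years; the correlation pairs each student's total
#' restorations with their consistency in the final simulated/observed year.
#'
#' @param input Path to an observation CSV (mutually exclusive with
#'   `config`).
#' @param config A [simulation_config()] object to generate data instead of
#'   reading it.
#' @param di_threshold Independence threshold for consistency (default 5).
#' @param alpha Significance level used by all tests.
#' @param out_dir Optional output directory for the report bundle.
#' @param dialect Optional CSV schema dialect for [read_observations()].
#' @return Invisibly, a list: `observations`, `restorations`, `summaries`,
#'   `pooled_summaries`, `difficulty`, `assignments`, `group_table`,
#'   `year_table`, `tests` (list: `ks_volume`, `ks_consistency`, `anova`,
#'   `correlation`), `log` (named counts). Stages whose preconditions the
#'   dataset cannot meet (fewer than two cohorts or years, no student with
#'   40+ restorations, degenerate variances) are `NULL` rather than errors.
#' @export
run_pipeline <- function(input = NULL, config = NULL, di_threshold = 5L,
                         alpha = 0.05, out_dir = NULL, dialect = NULL) {
  if (is.null(input) == is.null(config)) {
    abort("Supply exactly one of `input` (a CSV path) or `config`.",
          class = "consistr_config_error")
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)),
            class = "consistr_pipeline_error", parent = e)
    })
  }
  obs <- if (!is.null(input)) {
    stage("read", read_observations(input, dialect = dialect))
  } else {
    stage("simulate", simulate_cohorts(config))
  }
  restorations <- stage("assemble", assemble_restorations(obs, keep_stages = FALSE))
  summaries <- stage("consistency",
                     summarize_student_years(restorations, di_threshold))
  pooled <- stage("consistency",
                  summarize_student_years(restorations, di_threshold,
                                          pool_years = TRUE))
  diff <- stage("difficulty", difficulty_summary(restorations))
  assignments <- stage("stratify", group_assignments(restorations))
  group_table <- if (any(assignments$group != "excluded")) {
    stage("stratify", group_descriptives(restorations))
  } else {
    NULL
  }
  year_table <- summaries |>
    group_by(.data$year_of_study) |>
    summarise(
      n_students = n(),
      mean_consistency = mean(.data$consistency),
      sd_consistency = stats::sd(.data$consistency),
      median_restorations = stats::median(.data$n_restorations),
      .groups = "drop"
    )

  cohorts <- sort(unique(restorations$cohort_id))
  ks_volume <- ks_consistency <- NULL
  if (length(cohorts) == 2L) {
    by_cohort <- function(df, col) {
      lapply(cohorts, function(cid) df[[col]][df$cohort_id == cid])
    }
    v <- by_cohort(pooled, "n_restorations")
    ks_volume <- stage("ks", ks_cohort_check(v[[1]], v[[2]], alpha))
    cc <- by_cohort(pooled, "consistency")
    ks_consistency <- stage("ks", ks_cohort_check(cc[[1]], cc[[2]], alpha))
  }
  anova_res <- NULL
  year_counts <- table(summaries$year_of_study)
  if (length(year_counts) >= 2L && all(year_counts >= 2L) &&
      stats::var(summaries$consistency) > 0) {
    anova_res <- stage("anova", year_effect_anova(summaries, alpha))
  }
  final_year <- max(summaries$year_of_study)
  final <- inner_join(
    pooled |> select("student_id", total_restorations = "n_restorations"),
    summaries |>
      filter(.data$year_of_study == final_year) |>
      select("student_id", "consistency"),
    by = "student_id"
  )
  correlation <- NULL
  if (nrow(final) >= 3L && stats::sd(final$total_restorations) > 0 &&
      stats::sd(final$consistency) > 0) {
    correlation <- stage(
      "correlation",
      volume_consistency_correlation(final$total_restorations,
                                     final$consistency, alpha)
    )
  }

  log <- c(
    n_observations = nrow(obs),
    n_restorations = nrow(restorations),
    n_students = dplyr::n_distinct(obs$student_id),
    n_cohorts = length(cohorts),
    n_excluded_students = sum(assignments$group == "excluded"),
    final_year = final_year
  )
  result <- list(
    observations = obs,
    restorations = restorations,
    summaries = summaries,
    pooled_summaries = pooled,
    difficulty = diff,
    assignments = assignments,
    group_table = group_table,
    year_table = year_table,
    tests = list(ks_volume = ks_volume, ks_consistency = ks_consistency,
                 anova = anova_res, correlation = correlation),
    log = log
  )
  if (!is.null(out_dir)) {
    write_report_bundle(result, out_dir, simulated = is.null(input))
  }
  invisible(result)
}

write_report_bundle <- function(result, out_dir, simulated) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (simulated) {
    write_observations(result$observations,
                       file.path(out_dir, "observations.csv"))
  }
  readr::write_csv(result$summaries, file.path(out_dir, "summaries.csv"),
                   progress = FALSE)
  readr::write_csv(result$difficulty, file.path(out_dir, "difficulty.csv"),
                   progress = FALSE)
  if (!is.null(result$group_table)) {
    readr::write_csv(result$group_table, file.path(out_dir, "table_groups.csv"),
                     progress = FALSE)
  }
  readr::write_csv(result$year_table, file.path(out_dir, "table_years.csv"),
                   progress = FALSE)
  tests <- result$tests
  json <- jsonlite::toJSON(
    list(
      ks_volume = tests$ks_volume,
      ks_consistency = tests$ks_consistency,
      anova_overall = if (!is.null(tests$anova)) tests$anova$overall,
      anova_pairwise = if (!is.null(tests$anova)) tests$anova$pairwise,
      correlation = tests$correlation,
      counts = as.list(result$log)
    ),
    auto_unbox = TRUE, digits = 10, pretty = TRUE, null = "null"
  )
  writeLines(json, file.path(out_dir, "tests.json"))
  log_lines <- sprintf("%s: %s", names(result$log),
                       format(result$log, trim = TRUE))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(out_dir)
}
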