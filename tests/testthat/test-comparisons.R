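# Brute-force two-sample KS statistic: sup of |ECDF difference| over the
# pooled sample points.
oracle_ks_D <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(vapply(pts, function(t) {
    abs(mean(x <= t) - mean(y <= t))
  }, 1))
}

test_that("KS check: identical samples give D = 0, disjoint give D = 1", {
  x <- c(0.2, 0.4, 0.6)
  same <- ks_cohort_check(x, x)
  expect_equal(same$statistic, 0)
  expect_true(same$pool)
  far <- ks_cohort_check(rep(0, 20), rep(1, 20))
  expect_equal(far$statistic, 1)
  expect_false(far$pool)
  expect_error(ks_cohort_check(numeric(), x), class = "consistr_empty_error")
})

test_that("KS statistic matches the brute-force supremum on random samples", {
  set.seed(41)
  for (i in 1:200) {
    x <- round(runif(sample(3:25, 1)), 2)   # rounding induces ties
    y <- round(runif(sample(3:25, 1)), 2)
    expect_equal(ks_cohort_check(x, y)$statistic, oracle_ks_D(x, y))
  }
})

test_that("ANOVA input guards: too few years, too few students, no variance", {
  one_year <- tibble::tibble(year_of_study = 5L, consistency = runif(10))
  expect_error(year_effect_anova(one_year),
               class = "consistr_degenerate_error")
  thin <- tibble::tibble(year_of_study = c(3L, 3L, 4L),
                         consistency = c(0.5, 0.6, 0.7))
  expect_error(year_effect_anova(thin), class = "consistr_degenerate_error")
  flat <- tibble::tibble(year_of_study = rep(c(3L, 4L), each = 5),
                         consistency = 0.5)
  expect_error(year_effect_anova(flat), class = "consistr_degenerate_error")
})

test_that("with two balanced groups the ANOVA F is the squared pooled t", {
  set.seed(42)
  for (i in 1:20) {
    s <- tibble::tibble(
      year_of_study = rep(c(3L, 4L), each = 15),
      consistency = round(runif(30), 2)
    )
    if (var(s$consistency) == 0) next
    fit <- year_effect_anova(s)
    tt <- t.test(consistency ~ year_of_study, data = s, var.equal = TRUE)
    expect_equal(fit$overall$statistic, unname(tt$statistic)^2)
    expect_equal(fit$overall$p_value, tt$p.value)
  }
})

test_that("Bonferroni-adjusted p-values never fall below the raw ones", {
  set.seed(43)
  s <- tibble::tibble(
    year_of_study = rep(3:5, each = 20),
    consistency = runif(60)
  )
  fit <- year_effect_anova(s)
  expect_equal(nrow(fit$pairwise), 3L)
  expect_true(all(fit$pairwise$p_bonferroni >= fit$pairwise$p_value))
  expect_true(all(fit$pairwise$p_bonferroni <= 1))
  expect_equal(fit$pairwise$p_bonferroni,
               pmin(1, 3 * fit$pairwise$p_value))
  expect_equal(fit$pairwise$mean_diff_pct, 100 * fit$pairwise$mean_diff)
})

test_that("correlation matches direct summation and flags degenerate input", {
  expect_equal(volume_consistency_correlation(1:10, (1:10) / 10)$r, 1)
  expect_equal(volume_consistency_correlation(c(1, 2, 3), c(3, 2, 1))$r, -1)
  expect_error(volume_consistency_correlation(c(1, 2), c(1, 2)),
               class = "consistr_degenerate_error")
  expect_error(volume_consistency_correlation(rep(2, 5), runif(5)),
               class = "consistr_degenerate_error")
  set.seed(44)
  for (i in 1:100) {
    n <- sample(4:30, 1)
    x <- rnorm(n); y <- rnorm(n)
    got <- volume_consistency_correlation(x, y)
    # oracle: covariance / sd formula by direct summation
    r_direct <- (sum(x * y) - n * mean(x) * mean(y)) /
      ((n - 1) * sd(x) * sd(y))
    expect_equal(got$r, r_direct)
    expect_equal(got$slope, r_direct * sd(y) / sd(x))
  }
})

test_that("the pipeline produces a complete, internally consistent report", {
  cfg <- small_config(seed = 9L)
  out <- withr::local_tempdir()
  rep1 <- run_pipeline(config = cfg, out_dir = out)
  expect_true(all(c("summaries.csv", "difficulty.csv", "table_groups.csv",
                    "table_years.csv", "tests.json", "run.log",
                    "observations.csv") %in% list.files(out)))
  expect_equal(unname(rep1$log["n_observations"]), nrow(rep1$observations))
  expect_equal(unname(rep1$log["n_restorations"]), nrow(rep1$restorations))
  expect_equal(sum(rep1$summaries$n_restorations), nrow(rep1$restorations))
  expect_s3_class(rep1$tests$ks_volume, "tbl_df")
  expect_s3_class(rep1$tests$anova$overall, "tbl_df")
  expect_s3_class(rep1$tests$correlation, "tbl_df")
  expect_true(all(c("1", "2", "3", "4", "total") %in% rep1$group_table$group |
                    rep1$group_table$group %in% c("1", "2", "3", "4", "total")))

  # determinism: identical seed reproduces the bundle byte for byte
  out2 <- withr::local_tempdir()
  run_pipeline(config = cfg, out_dir = out2)
  for (f in c("observations.csv", "tests.json", "summaries.csv")) {
    expect_identical(readLines(file.path(out, f)),
                     readLines(file.path(out2, f)))
  }
})

test_that("the pipeline reproduces the worked example from a CSV input", {
  path <- system.file("extdata", "final_year_example.csv",
                      package = "consistr")
  rep <- run_pipeline(input = path)
  expect_equal(rep$summaries$consistency, 0.6)
  expect_equal(rep$summaries$n_restorations, 10L)
  expect_null(rep$tests$ks_volume)   # single cohort: no KS stage
  expect_null(rep$tests$anova)       # single year: no ANOVA stage
})

test_that("pipeline errors carry the failing stage name", {
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("student_id,di\nS1,7", bad)
  err <- expect_error(run_pipeline(input = bad),
                      class = "consistr_pipeline_error")
  expect_match(conditionMessage(err), "stage 'read'")
  expect_error(run_pipeline(), class = "consistr_config_error")
})
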