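# Statistical comparison stages: cohort distributional equivalence,
# year-of-study effect on consistency, and the volume-vs-consistency
# correlation.

#' Two-sample Kolmogorov-Smirnov check of cohort equivalence
#'
#' Compares the distributions of a per-student quantity (restoration counts
#' or consistency values) between two cohorts, to decide whether the cohorts
#' can be pooled before further analysis. The statistic is
#' D = sup |ECDF_A - ECDF_B|; the asymptotic p-value is used by default,
#' appropriate for cohort sizes near 70 (ordinal-derived values are tied, so
#' the exact p-value is unavailable anyway).
#'
#' @param x,y Numeric samples (one per cohort), both non-empty.
#' @param alpha Significance level for the pooling decision; cohorts are
#'   pooled when p > alpha.
#' @param exact Passed to [stats::ks.test()]; default `FALSE` (asymptotic).
#' @return A one-row tibble: `test`, `statistic` (D), `p_value`, `alpha`,
#'   `pool` (logical pooling decision), `adjusted` (always `FALSE`).
#' @export
ks_cohort_check <- function(x, y, alpha = 0.05, exact = FALSE) {
  if (length(x) == 0L || length(y) == 0L) {
    abort("Both cohort samples must be non-empty.",
          class = "consistr_empty_error")
  }
  res <- suppressWarnings(stats::ks.test(x, y, exact = exact))
  tibble(
    test = "two-sample Kolmogorov-Smirnov",
    statistic = unname(res$statistic),
    p_value = unname(res$p.value),
    alpha = alpha,
    pool = unname(res$p.value) > alpha,
    adjusted = FALSE
  )
}

#' Year-of-study effect on consistency
#'
#' One-way ANOVA of per-student yearly consistency values across years of
#' study, followed by all pairwise year contrasts as Welch t-tests with
#' Bonferroni correction (adjusted p = min(1, m * raw p) for m pairwise
#' comparisons). Each student contributes one value per year; the years are
#' treated as independent groups — the repeated-measures structure of a
#' longitudinal cohort is deliberately ignored, a known simplification of
#' this classical analysis.
#'
#' Mean differences are reported both as proportions and on the percentage
#' scale (a 0.14 increase in consistency is a 14-point increase).
#'
#' @param summaries A tibble from [summarize_student_years()] with
#'   `year_of_study` and `consistency` columns.
#' @param alpha Significance level.
#' @return A list with elements `overall` (one-row tibble: F statistic,
#'   degrees of freedom, p-value) and `pairwise` (one row per year pair:
#'   `mean_diff`, `mean_diff_pct`, Welch `statistic`, `p_value`,
#'   `p_bonferroni`, `significant`).
#' @export
year_effect_anova <- function(summaries, alpha = 0.05) {
  counts <- table(summaries$year_of_study)
  if (length(counts) < 2L) {
    abort("At least two years of study are required.",
          class = "consistr_degenerate_error")
  }
  if (any(counts < 2L)) {
    abort(sprintf("Every year needs >= 2 students; year(s) %s have fewer.",
                  paste(names(counts)[counts < 2L], collapse = ", ")),
          class = "consistr_degenerate_error")
  }
  if (stats::var(summaries$consistency) == 0) {
    abort("All consistency values are identical; the F statistic is undefined.",
          class = "consistr_degenerate_error")
  }
  fit <- stats::lm(consistency ~ factor(year_of_study), data = summaries)
  an <- stats::anova(fit)
  overall <- tibble(
    test = "one-way ANOVA (year of study)",
    statistic = an$`F value`[1],
    df_between = an$Df[1],
    df_within = an$Df[2],
    p_value = an$`Pr(>F)`[1],
    alpha = alpha,
    significant = an$`Pr(>F)`[1] < alpha
  )
  years <- sort(unique(summaries$year_of_study))
  pairs <- utils::combn(years, 2L)
  m <- ncol(pairs)
  pairwise <- lapply(seq_len(m), function(j) {
    a <- summaries$consistency[summaries$year_of_study == pairs[1, j]]
    b <- summaries$consistency[summaries$year_of_study == pairs[2, j]]
    tt <- stats::t.test(b, a)  # Welch
    tibble(
      comparison = sprintf("year %d vs year %d", pairs[1, j], pairs[2, j]),
      mean_diff = mean(b) - mean(a),
      mean_diff_pct = 100 * (mean(b) - mean(a)),
      statistic = unname(tt$statistic),
      p_value = unname(tt$p.value),
      p_bonferroni = min(1, m * unname(tt$p.value)),
      alpha = alpha,
      significant = min(1, m * unname(tt$p.value)) < alpha
    )
  })
  list(overall = overall, pairwise = bind_rows(pairwise))
}

#' Correlation of restoration volume with final-year consistency
#'
#' Pearson correlation (with two-sided p-value) between each student's total
#' number of restorations and their final-year consistency, plus the fitted
#' least-squares line for plotting.
#'
#' @param total_restorations,consistency Paired numeric vectors, one element
#'   per student, n >= 3.
#' @param alpha Significance level.
#' @return A one-row tibble: `r`, `statistic` (t), `df`, `p_value`, `slope`,
#'   `intercept`, `n`, `alpha`, `significant`.
#' @export
volume_consistency_correlation <- function(total_restorations, consistency,
                                           alpha = 0.05) {
  if (length(total_restorations) != length(consistency)) {
    abort("Paired vectors must have equal length.",
          class = "consistr_validation_error")
  }
  if (length(total_restorations) < 3L) {
    abort("At least 3 paired values are required.",
          class = "consistr_degenerate_error")
  }
  if (stats::sd(total_restorations) == 0 || stats::sd(consistency) == 0) {
    abort("Correlation is undefined when either variable has zero variance.",
          class = "consistr_degenerate_error")
  }
  ct <- stats::cor.test(total_restorations, consistency, method = "pearson")
  fit <- stats::lm(consistency ~ total_restorations)
  tibble(
    test = "Pearson correlation (volume vs final-year consistency)",
    r = unname(ct$estimate),
    statistic = unname(ct$statistic),
    df = unname(ct$parameter),
    p_value = unname(ct$p.value),
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    n = length(total_restorations),
    alpha = alpha,
    significant = unname(ct$p.value) < alpha
  )
}
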