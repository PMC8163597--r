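# The consistency statistic: binarize each restoration by its weakest stage
# against an independence threshold, then average per student (per year).

check_threshold <- function(di_threshold) {
  if (!(length(di_threshold) == 1L && di_threshold %in% 1:6)) {
    abort("`di_threshold` must be a single DI value in 1-6.",
          class = "consistr_config_error")
  }
  as.integer(di_threshold)
}

#' Independence indicator for restorations
#'
#' A restoration counts as independently completed (indicator 1) if and only
#' if its lowest stage DI is at or above the threshold: every stage must have
#' been performed independently at the required quality. Any stage below the
#' threshold returns the whole restoration as 0. The default threshold of 5
#' is the DI level representing independence.
#'
#' @param restorations A restorations tibble from [assemble_restorations()]
#'   (any data frame with a `min_di` column).
#' @param di_threshold Integer DI threshold in 1-6; default 5.
#' @return Integer vector of 0/1 indicators, one per restoration.
#' @export
#' @examples
#' r <- tibble::tibble(min_di = c(4L, 5L, 6L))
#' independence_indicator(r)
independence_indicator <- function(restorations, di_threshold = 5L) {
  thr <- check_threshold(di_threshold)
  as.integer(restorations$min_di >= thr)
}

#' Consistency score of a set of restorations
#'
#' The fraction of restorations whose minimum stage DI meets the independence
#' threshold, i.e. the mean of [independence_indicator()]. Ten restorations
#' with lowest DIs 4, 3, 5, 5, 6, 6, 4, 5, 4, 6 at threshold 5 give
#' indicators 0, 0, 1, 1, 1, 1, 0, 1, 0, 1 and a consistency of 6/10 = 0.6.
#'
#' The statistic is undefined on an empty set; an empty input raises an error
#' of class `consistr_empty_error` rather than returning 0.
#'
#' @inheritParams independence_indicator
#' @return A single number in `[0, 1]`.
#' @export
consistency_score <- function(restorations, di_threshold = 5L) {
  if (nrow(restorations) == 0L) {
    abort("Consistency is undefined for an empty set of restorations.",
          class = "consistr_empty_error")
  }
  mean(independence_indicator(restorations, di_threshold))
}

#' Per-student (per-year) consistency summaries
#'
#' Partitions restorations by student and, by default, year of study, and
#' returns for each cell the restoration count, the number of independently
#' completed restorations, and the consistency. Students with no restorations
#' in a year simply have no row for that year (consistency is undefined on an
#' empty set), so the summaries partition the input exactly.
#'
#' @inheritParams independence_indicator
#' @param pool_years If `TRUE`, pool all years of study into a single overall
#'   summary per student (used e.g. for cohort-equivalence checks).
#' @return A tibble with columns `student_id`, `cohort_id`,
#'   `year_of_study` (unless pooled), `n_restorations`, `n_independent`,
#'   `consistency`.
#' @export
summarize_student_years <- function(restorations, di_threshold = 5L,
                                    pool_years = FALSE) {
  keys <- c("student_id", "cohort_id", if (!pool_years) "year_of_study")
  restorations |>
    mutate(.ind = independence_indicator(restorations, di_threshold)) |>
    group_by(across(all_of(keys))) |>
    summarise(
      n_restorations = n(),
      n_independent = sum(.data$.ind),
      consistency = .data$n_independent / .data$n_restorations,
      .groups = "drop"
    ) |>
    arrange(across(all_of(keys)))
}

#' Cumulative distribution of student consistency
#'
#' Empirical cumulative distribution of per-student consistency for one year
#' of study (or for all summaries supplied): at each distinct consistency
#' value, the cumulative percentage of students at or below it. The curve is
#' non-decreasing and ends at 100%.
#'
#' @param summaries A summary tibble from [summarize_student_years()].
#' @param year Optional year of study to restrict to.
#' @return A tibble with columns `consistency`, `n_students` (at that exact
#'   level) and `cum_pct`.
#' @export
cumulative_consistency_distribution <- function(summaries, year = NULL) {
  s <- summaries
  if (!is.null(year)) {
    s <- filter(s, .data$year_of_study == year)
  }
  if (nrow(s) == 0L) {
    abort("No student summaries for the requested year.",
          class = "consistr_empty_error")
  }
  levels <- sort(unique(s$consistency))
  tibble(
    consistency = levels,
    n_students = vapply(levels, function(v) sum(s$consistency == v),
                        integer(1)),
    cum_pct = 100 * stats::ecdf(s$consistency)(levels)
  )
}
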