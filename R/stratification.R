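# Experience-group assignment and stratified descriptive statistics.

#' Assign students to experience groups by total restorations
#'
#' Total restorations across all years and cohorts map to groups:
#' group 1 = 40-49, group 2 = 50-59, group 3 = 60-69, group 4 = 70 or more.
#' Totals below 40 are `excluded` from group-level analysis.
#'
#' @param total_restorations Integer vector of per-student totals (>= 0).
#' @return Factor with levels `"1"`, `"2"`, `"3"`, `"4"`, `"excluded"`.
#' @export
#' @examples
#' assign_group(c(39, 40, 55, 70, 120))
assign_group <- function(total_restorations) {
  if (any(is.na(total_restorations)) || any(total_restorations < 0)) {
    abort("Total restorations must be non-negative.",
          class = "consistr_validation_error")
  }
  lab <- ifelse(total_restorations < 40, "excluded",
         ifelse(total_restorations < 50, "1",
         ifelse(total_restorations < 60, "2",
         ifelse(total_restorations < 70, "3", "4"))))
  factor(lab, levels = c("1", "2", "3", "4", "excluded"))
}

#' Per-student totals and group assignments
#'
#' @param restorations A restorations tibble from [assemble_restorations()].
#' @return A tibble with `student_id`, `cohort_id`, `total_restorations`,
#'   `group`.
#' @export
group_assignments <- function(restorations) {
  restorations |>
    group_by(.data$student_id, .data$cohort_id) |>
    summarise(total_restorations = n(), .groups = "drop") |>
    mutate(group = assign_group(.data$total_restorations)) |>
    arrange(.data$student_id)
}

#' Stratified descriptive statistics by experience group
#'
#' For each experience group (and a pooled `total` column) computes, over the
#' students in the group: median (min-max) of the per-student count of
#' restorations in each surface class and each quadrant, mean +/- SD of the
#' per-student difficult-restoration count and percentage, and the number of
#' students. Per-student counts are tallied first (a student with no
#' restorations of a surface counts 0 for it); the group statistics are then
#' taken over students. Excluded students (total < 40) appear in no group
#' column and, by default, not in the `total` column either.
#'
#' @inheritParams group_assignments
#' @param include_excluded_in_total Also include excluded students in the
#'   pooled `total` column? Default `FALSE`.
#' @return A long tibble with columns `group` (`"1"`-`"4"`, `"total"`),
#'   `measure` (`"surface"`, `"quadrant"`, `"difficulty_n"`,
#'   `"difficulty_pct"`, `"students"`), `level` (surface label, quadrant
#'   number, or `NA`), `n_students`, `median`, `min`, `max`, `mean`, `sd`.
#'   The SD is the sample (n-1) standard deviation.
#' @export
group_descriptives <- function(restorations,
                               include_excluded_in_total = FALSE) {
  assignments <- group_assignments(restorations)
  included <- filter(assignments, .data$group != "excluded")
  if (nrow(included) == 0L) {
    abort("No students with 40 or more restorations to stratify.",
          class = "consistr_empty_error")
  }

  per_student_counts <- function(var) {
    lv <- if (var == "surface") surface_classes() else 1:4
    restorations |>
      group_by(.data$student_id, level = as.character(.data[[var]])) |>
      summarise(count = n(), .groups = "drop") |>
      tidyr::complete(
        student_id = unique(restorations$student_id),
        level = as.character(lv),
        fill = list(count = 0L)
      )
  }
  counts <- bind_rows(
    mutate(per_student_counts("surface"), measure = "surface"),
    mutate(per_student_counts("quadrant"), measure = "quadrant")
  )
  diffs <- difficulty_summary(restorations)

  one_column <- function(students, label) {
    cell_counts <- counts |>
      filter(.data$student_id %in% students) |>
      group_by(.data$measure, .data$level) |>
      summarise(
        n_students = n_distinct(.data$student_id),
        median = stats::median(.data$count),
        min = min(.data$count),
        max = max(.data$count),
        mean = NA_real_, sd = NA_real_,
        .groups = "drop"
      )
    d <- filter(diffs, .data$student_id %in% students)
    cell_diff <- tibble(
      measure = c("difficulty_n", "difficulty_pct"),
      level = NA_character_,
      n_students = nrow(d),
      median = c(stats::median(d$n_difficult), stats::median(d$pct_difficult)),
      min = c(min(d$n_difficult), min(d$pct_difficult)),
      max = c(max(d$n_difficult), max(d$pct_difficult)),
      mean = c(mean(d$n_difficult), mean(d$pct_difficult)),
      sd = c(stats::sd(d$n_difficult), stats::sd(d$pct_difficult))
    )
    cell_n <- tibble(
      measure = "students", level = NA_character_,
      n_students = length(students),
      median = NA_real_, min = NA_real_, max = NA_real_,
      mean = NA_real_, sd = NA_real_
    )
    mutate(bind_rows(cell_counts, cell_diff, cell_n), group = label)
  }

  columns <- lapply(c("1", "2", "3", "4"), function(g) {
    students <- included$student_id[included$group == g]
    if (length(students) == 0L) return(NULL)
    one_column(students, g)
  })
  total_students <- if (include_excluded_in_total) {
    assignments$student_id
  } else {
    included$student_id
  }
  columns <- c(columns, list(one_column(total_students, "total")))
  bind_rows(columns) |>
    select("group", "measure", "level", "n_students",
           "median", "min", "max", "mean", "sd")
}
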