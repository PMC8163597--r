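# Shared builders for small in-code fixtures.

# Restoration-level tibble with the columns the analysis modules use.
make_restorations <- function(min_dis,
                              student_id = "S001",
                              cohort_id = "cohort1",
                              year_of_study = 5L,
                              quadrant = 3L,
                              tooth = 5L,
                              surface = "occlusal_surface",
                              staff_difficult_flag = FALSE) {
  n <- length(min_dis)
  tibble::tibble(
    restoration_id = sprintf("R%04d", seq_len(n)),
    student_id = rep_len(student_id, n),
    cohort_id = rep_len(cohort_id, n),
    year_of_study = as.integer(rep_len(year_of_study, n)),
    staff_id = "ST01",
    patient_id = "P01",
    quadrant = as.integer(rep_len(quadrant, n)),
    tooth = as.integer(rep_len(tooth, n)),
    surface = rep_len(surface, n),
    staff_difficult_flag = rep_len(staff_difficult_flag, n),
    n_stages = 1L,
    min_di = as.integer(min_dis)
  )
}

# Observation-level tibble: one restoration id per element of `dis`, each a
# vector of stage DI scores.
make_observations <- function(dis, student_id = "S001", year_of_study = 5L,
                              quadrant = 3L, tooth = 5L,
                              surface = "occlusal_surface",
                              staff_difficult_flag = FALSE) {
  rows <- lapply(seq_along(dis), function(i) {
    tibble::tibble(
      student_id = student_id,
      cohort_id = "cohort1",
      year_of_study = as.integer(year_of_study),
      staff_id = "ST01",
      patient_id = "P01",
      restoration_id = sprintf("R%04d", i),
      stage_id = sprintf("stage%02d", seq_along(dis[[i]])),
      di = as.integer(dis[[i]]),
      quadrant = as.integer(quadrant),
      tooth = as.integer(tooth),
      surface = surface,
      material = "composite",
      staff_difficult_flag = staff_difficult_flag
    )
  })
  dplyr::bind_rows(rows)
}

# A random restoration set exercising all surfaces/quadrants/positions.
random_restorations <- function(n, n_students = 3L, years = 3:5) {
  cohort_of <- stats::setNames(
    sample(c("cohort1", "cohort2"), n_students, replace = TRUE),
    sprintf("S%02d", seq_len(n_students))
  )
  student <- sample(sprintf("S%02d", seq_len(n_students)), n, replace = TRUE)
  tibble::tibble(
    restoration_id = sprintf("R%04d", seq_len(n)),
    student_id = student,
    cohort_id = unname(cohort_of[student]),
    year_of_study = sample(as.integer(years), n, replace = TRUE),
    staff_id = sample(sprintf("ST%02d", 1:5), n, replace = TRUE),
    patient_id = sample(sprintf("P%02d", 1:8), n, replace = TRUE),
    quadrant = sample(1:4, n, replace = TRUE),
    tooth = sample(1:8, n, replace = TRUE),
    surface = sample(surface_classes(), n, replace = TRUE),
    staff_difficult_flag = sample(c(TRUE, FALSE), n, replace = TRUE,
                                  prob = c(0.1, 0.9)),
    n_stages = 1L,
    min_di = sample(1:6, n, replace = TRUE)
  )
}

# Scaled-down simulation configuration for fast unit tests.
small_config <- function(seed = 7L, ...) {
  simulation_config(
    n_students_per_cohort = 10L,
    n_cohorts = 2L,
    n_staff_pool = 15L,
    ...,
    seed = seed
  )
}
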