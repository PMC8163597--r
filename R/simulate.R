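# Seeded synthetic-cohort generator. Emulates multi-year observation data
# from supervised restorative clinics: students with latent ability that
# grows by year of study, hawk/dove rater offsets, a case mix over surfaces,
# quadrants and tooth positions, and ordinal DI scores emitted per procedure
# stage through a latent-threshold (cumulative-link) mechanism.

#' Build and validate a synthetic-cohort configuration
#'
#' Defaults describe two graduating cohorts of 70 students observed over
#' clinical years 3-5, with per-year restoration volumes whose medians fall
#' near 16/24/16, roughly ten (+/- 3) distinct supervising staff per student,
#' and year-of-study ability growth calibrated so that per-year mean student
#' consistencies at threshold 5 come out near 0.46, 0.60 and 0.76 (SD about
#' 0.18/0.16/0.14) — the regime of a realistic undergraduate cohort.
#'
#' Stage DI scores are emitted by discretising a latent performance level
#' through fixed cut-points: the latent level is the student intercept plus
#' the student-year ability term plus the year increment, minus a difficulty
#' penalty when the generated restoration satisfies the difficulty rule used
#' by the analysis ([is_difficult()]), minus the staff hawk/dove offset, plus
#' per-stage noise. The cut-points map the latent scale to DI 1-6; DI >= 5
#' corresponds to latent values above the fourth cut-point.
#'
#' @param n_students_per_cohort Students per cohort.
#' @param n_cohorts Number of cohorts.
#' @param years Years of study simulated (subset of 3:5, non-empty).
#' @param restorations_per_year Named numeric vector of Poisson means for the
#'   per-student restoration count in each year.
#' @param stages_per_restoration Number of judged stages per restoration.
#' @param n_staff_pool Size of the supervising staff pool.
#' @param staff_per_student Named vector `c(mean, sd)` for the size of each
#'   student's staff subset (clipped normal, minimum 1).
#' @param ability List: `intercept_mean`, `intercept_sd` (persistent
#'   per-student ability), `year_sd` (per student-year variation, e.g.
#'   patient-mix luck), and `year_increments` (named per-year means of the
#'   latent level).
#' @param rater_sd SD of per-staff hawk/dove offsets (subtracted from the
#'   latent level, so a positive offset is a hawk).
#' @param di_noise SD of the per-stage latent noise.
#' @param cutpoints Increasing vector of 5 cut-points mapping the latent
#'   scale to DI 1-6.
#' @param difficulty_penalty Latent penalty applied to restorations that
#'   satisfy the difficulty rule.
#' @param case_mix List of probability vectors: `surface` (named by
#'   [surface_classes()]), `quadrant` (length 4) and `position` (length 8).
#'   Each must sum to 1.
#' @param staff_flag_rate Probability a restoration is staff-tagged difficult
#'   for an external reason.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   configuration.
#' @return A validated configuration object of class `simulation_config`.
#' @export
simulation_config <- function(
    n_students_per_cohort = 70L,
    n_cohorts = 2L,
    years = 3:5,
    restorations_per_year = c(`3` = 16.5, `4` = 24.5, `5` = 16.5),
    stages_per_restoration = 3L,
    n_staff_pool = 40L,
    staff_per_student = c(mean = 10, sd = 3),
    ability = list(
      intercept_mean = 0,
      intercept_sd = 0.05,
      year_sd = 0.12,
      year_increments = c(`3` = 0.55, `4` = 0.72, `5` = 0.94)
    ),
    rater_sd = 0.15,
    di_noise = 0.55,
    cutpoints = c(-2.2, -1.5, -0.8, 0, 1.1),
    difficulty_penalty = 0.25,
    case_mix = list(
      surface = c(
        approximal_anterior = 0.18, approximal_posterior = 0.29,
        incisal_edge = 0.12, smooth_surface = 0.27, occlusal_surface = 0.14
      ),
      quadrant = c(0.27, 0.28, 0.23, 0.22),
      position = c(0.25, 0.22, 0.21, 0.08, 0.07, 0.07, 0.06, 0.04)
    ),
    staff_flag_rate = 0.02,
    seed = 1L) {
  cfg <- list(
    n_students_per_cohort = as.integer(n_students_per_cohort),
    n_cohorts = as.integer(n_cohorts),
    years = sort(as.integer(years)),
    restorations_per_year = restorations_per_year,
    stages_per_restoration = as.integer(stages_per_restoration),
    n_staff_pool = as.integer(n_staff_pool),
    staff_per_student = staff_per_student,
    ability = ability,
    rater_sd = rater_sd,
    di_noise = di_noise,
    cutpoints = cutpoints,
    difficulty_penalty = difficulty_penalty,
    case_mix = case_mix,
    staff_flag_rate = staff_flag_rate,
    seed = as.integer(seed)
  )
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  fail <- function(msg) abort(msg, class = "consistr_config_error")
  if (length(cfg$years) == 0L || !all(cfg$years %in% 3:5)) {
    fail("`years` must be a non-empty subset of 3:5.")
  }
  if (cfg$n_students_per_cohort < 0L || cfg$n_cohorts < 1L) {
    fail("Cohort sizes must be non-negative and n_cohorts >= 1.")
  }
  if (!all(as.character(cfg$years) %in% names(cfg$restorations_per_year))) {
    fail("`restorations_per_year` must name every simulated year.")
  }
  if (any(cfg$restorations_per_year < 0)) {
    fail("Restoration volumes must be non-negative.")
  }
  if (cfg$stages_per_restoration < 1L) {
    fail("`stages_per_restoration` must be >= 1.")
  }
  if (cfg$n_staff_pool < 1L) fail("`n_staff_pool` must be >= 1.")
  if (!all(as.character(cfg$years) %in% names(cfg$ability$year_increments))) {
    fail("`ability$year_increments` must name every simulated year.")
  }
  if (length(cfg$cutpoints) != 5L || is.unsorted(cfg$cutpoints, strictly = TRUE)) {
    fail("`cutpoints` must be 5 strictly increasing values.")
  }
  check_probs <- function(p, what, len = NULL) {
    if (!is.null(len) && length(p) != len) {
      fail(sprintf("`case_mix$%s` must have length %d.", what, len))
    }
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      fail(sprintf("`case_mix$%s` must be non-negative and sum to 1.", what))
    }
  }
  check_probs(cfg$case_mix$surface, "surface", 5L)
  if (!setequal(names(cfg$case_mix$surface), surface_classes())) {
    fail("`case_mix$surface` must be named by the five surface classes.")
  }
  check_probs(cfg$case_mix$quadrant, "quadrant", 4L)
  check_probs(cfg$case_mix$position, "position", 8L)
  if (cfg$staff_flag_rate < 0 || cfg$staff_flag_rate > 1) {
    fail("`staff_flag_rate` must be a probability.")
  }
  invisible(cfg)
}

#' Simulate multi-year observation data
#'
#' Draws a full observation-level dataset (one row per judged stage) from the
#' generative model described in [simulation_config()]. The output passes
#' [validate_observations()] and feeds directly into
#' [assemble_restorations()]. All randomness flows from `config$seed` through
#' a single stream with a fixed draw order, so identical configurations give
#' byte-identical datasets.
#'
#' @param config A `simulation_config` object.
#' @return An observations tibble in the canonical schema.
#' @export
simulate_cohorts <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  validate_simulation_config(config)
  set.seed(config$seed)

  n_students <- config$n_students_per_cohort * config$n_cohorts
  if (n_students == 0L) {
    out <- coerce_observations(
      tibble(student_id = character(), cohort_id = character(),
             year_of_study = character(), staff_id = character(),
             patient_id = character(), restoration_id = character(),
             stage_id = character(), di = character(), quadrant = character(),
             tooth = character(), surface = character(),
             material = character(), staff_difficult_flag = character())
    )
    return(out)
  }

  students <- tibble(
    student_id = sprintf("S%03d", seq_len(n_students)),
    cohort_id = sprintf("cohort%d", rep(seq_len(config$n_cohorts),
                                        each = config$n_students_per_cohort)),
    intercept = stats::rnorm(n_students, config$ability$intercept_mean,
                             config$ability$intercept_sd)
  )
  staff_offsets <- stats::rnorm(config$n_staff_pool, 0, config$rater_sd)
  staff_ids <- sprintf("ST%02d", seq_len(config$n_staff_pool))

  # each student works with a clipped-normal-sized subset of the staff pool
  subset_sizes <- pmin(
    config$n_staff_pool,
    pmax(1L, round(stats::rnorm(n_students,
                                config$staff_per_student[["mean"]],
                                config$staff_per_student[["sd"]])))
  )
  staff_subsets <- lapply(subset_sizes, function(k) {
    sample.int(config$n_staff_pool, k)
  })

  years <- config$years
  student_years <- tidyr::expand_grid(
    idx = seq_len(n_students),
    year_of_study = years
  )
  student_years$n_rest <- stats::rpois(
    nrow(student_years),
    config$restorations_per_year[as.character(student_years$year_of_study)]
  )
  student_years$year_ability <- stats::rnorm(nrow(student_years), 0,
                                             config$ability$year_sd)

  sy <- student_years[student_years$n_rest > 0L, ]
  if (nrow(sy) == 0L) {
    abort("Simulated cohort produced no restorations; increase volumes.",
          class = "consistr_config_error")
  }
  n_rest_total <- sum(sy$n_rest)
  ridx <- rep.int(seq_len(nrow(sy)), sy$n_rest)
  rest <- tibble(
    idx = sy$idx[ridx],
    year_of_study = sy$year_of_study[ridx],
    year_ability = sy$year_ability[ridx]
  )
  # restoration ids numbered within student, across years
  rest <- rest |>
    group_by(.data$idx) |>
    mutate(rest_seq = dplyr::row_number()) |>
    ungroup()
  rest$restoration_id <- sprintf("%s_R%04d",
                                 students$student_id[rest$idx],
                                 rest$rest_seq)

  # supervising staff: uniform within the student's subset (flattened
  # subset list indexed arithmetically so the draw is one vectorised runif)
  flat_subsets <- unlist(staff_subsets)
  subset_start <- c(0L, cumsum(lengths(staff_subsets)))
  pick <- ceiling(stats::runif(nrow(rest)) * subset_sizes[rest$idx])
  rest$staff_idx <- flat_subsets[subset_start[rest$idx] + pick]

  # patient pool per student: roughly one patient per two restorations
  total_per_student <- tabulate(rest$idx, nbins = n_students)
  pool_size <- pmax(1L, ceiling(total_per_student / 2))
  rest$patient_id <- sprintf(
    "%s_P%02d", students$student_id[rest$idx],
    ceiling(stats::runif(nrow(rest)) * pool_size[rest$idx])
  )

  cm <- config$case_mix
  rest$surface <- sample(names(cm$surface), n_rest_total, replace = TRUE,
                         prob = cm$surface)
  rest$quadrant <- sample.int(4L, n_rest_total, replace = TRUE,
                              prob = cm$quadrant)
  rest$tooth <- sample.int(8L, n_rest_total, replace = TRUE,
                           prob = cm$position)
  rest$staff_difficult_flag <- stats::runif(n_rest_total) < config$staff_flag_rate
  rest$material <- sample(c("composite", "amalgam", "glass_ionomer"),
                          n_rest_total, replace = TRUE,
                          prob = c(0.6, 0.3, 0.1))

  difficult <- is_difficult(rest)
  latent <- students$intercept[rest$idx] +
    config$ability$year_increments[as.character(rest$year_of_study)] +
    rest$year_ability -
    config$difficulty_penalty * difficult -
    staff_offsets[rest$staff_idx]

  s <- config$stages_per_restoration
  z <- rep(latent, each = s) +
    stats::rnorm(n_rest_total * s, 0, config$di_noise)
  di <- findInterval(z, config$cutpoints) + 1L

  stage_of <- rep(seq_len(s), times = n_rest_total)
  obs_row <- rep(seq_len(n_rest_total), each = s)
  obs <- tibble(
    student_id = students$student_id[rest$idx][obs_row],
    cohort_id = students$cohort_id[rest$idx][obs_row],
    year_of_study = rest$year_of_study[obs_row],
    staff_id = staff_ids[rest$staff_idx][obs_row],
    patient_id = rest$patient_id[obs_row],
    restoration_id = rest$restoration_id[obs_row],
    stage_id = sprintf("stage%02d", stage_of),
    di = di,
    quadrant = rest$quadrant[obs_row],
    tooth = rest$tooth[obs_row],
    surface = rest$surface[obs_row],
    material = rest$material[obs_row],
    staff_difficult_flag = rest$staff_difficult_flag[obs_row]
  )
  obs
}

#' Summarise a generated (or real) observation dataset
#'
#' Descriptive checks of the structural targets the generator aims at:
#' per-year restoration volumes, distinct staff per student, and the surface
#' and quadrant mix.
#'
#' @param obs An observations tibble.
#' @return A list with elements `volumes` (per year: median/mean restorations
#'   per student), `staff_per_student` (mean, sd), `surface_mix` and
#'   `quadrant_mix` (fractions of restorations), `n_students`,
#'   `n_restorations`, `n_observations`.
#' @export
summarize_generated <- function(obs) {
  if (nrow(obs) == 0L) {
    abort("Cannot summarise an empty dataset.", class = "consistr_empty_error")
  }
  rest <- obs |>
    dplyr::distinct(.data$student_id, .data$year_of_study,
                    .data$restoration_id, .data$surface, .data$quadrant)
  volumes <- rest |>
    group_by(.data$student_id, .data$year_of_study) |>
    summarise(n = n(), .groups = "drop") |>
    group_by(.data$year_of_study) |>
    summarise(median_restorations = stats::median(.data$n),
              mean_restorations = mean(.data$n), .groups = "drop")
  staff <- obs |>
    group_by(.data$student_id) |>
    summarise(k = n_distinct(.data$staff_id), .groups = "drop")
  list(
    volumes = volumes,
    staff_per_student = c(mean = mean(staff$k), sd = stats::sd(staff$k)),
    surface_mix = prop.table(table(rest$surface)),
    quadrant_mix = prop.table(table(rest$quadrant)),
    n_students = n_distinct(obs$student_id),
    n_restorations = n_distinct(obs$restoration_id),
    n_observations = nrow(obs)
  )
}
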