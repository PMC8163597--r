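# Observation-level record handling: the canonical CSV schema, validation,
# FDI tooth-notation helpers, and assembly of stage observations into
# restoration-level records.

#' Canonical observation CSV schema
#'
#' One row per stage observation: a single staff judgement, on the ordinal
#' developmental-indicator (DI) scale 1-6, of one stage of one restoration.
#' Booleans are serialised as `true`/`false`; `surface` must be one of
#' [surface_classes()]; tooth sites use FDI notation split into `quadrant`
#' (1-4) and `tooth` position (1-8, central incisor to third molar).
#'
#' @return Character vector of canonical column names, in order.
#' @export
#' @examples
#' observation_schema()
observation_schema <- function() {
  c(
    "student_id", "cohort_id", "year_of_study", "staff_id", "patient_id",
    "restoration_id", "stage_id", "di", "quadrant", "tooth", "surface",
    "material", "staff_difficult_flag"
  )
}

#' The five analysed restoration surface classes
#'
#' @return Character vector of the five surface-class labels.
#' @export
surface_classes <- function() {
  c(
    "approximal_anterior", "approximal_posterior", "incisal_edge",
    "smooth_surface", "occlusal_surface"
  )
}

#' Surface and tooth-site predicates
#'
#' `is_approximal()` is true for either approximal surface class (a surface
#' between adjacent teeth). `is_upper_posterior()` is true for teeth in FDI
#' quadrant 1 or 2 at positions 4-8 (premolars and molars of the upper arch),
#' the sites most likely to require indirect vision.
#'
#' @param surface Character vector of surface-class labels.
#' @param quadrant,position Integer vectors: FDI quadrant (1-4) and tooth
#'   position (1-8).
#' @return Logical vector.
#' @export
is_approximal <- function(surface) {
  surface %in% c("approximal_anterior", "approximal_posterior")
}

#' @rdname is_approximal
#' @export
is_upper_posterior <- function(quadrant, position) {
  quadrant %in% c(1L, 2L) & position %in% 4:8
}

#' Parse two-digit FDI tooth codes
#'
#' Splits codes such as `"16"` (upper-right first molar) into quadrant and
#' position. Accepts character or numeric input.
#'
#' @param code Vector of two-digit FDI codes, e.g. `"16"`, `24`, `"48"`.
#' @return A tibble with integer columns `quadrant` and `position`.
#' @export
#' @examples
#' parse_fdi_tooth(c("16", "31"))
parse_fdi_tooth <- function(code) {
  code <- as.character(code)
  ok <- grepl("^[1-4][1-8]$", code)
  if (!all(ok)) {
    abort(
      c("Invalid FDI tooth code(s):",
        utils::head(sprintf("'%s'", code[!ok]), 5L)),
      class = "consistr_validation_error"
    )
  }
  tibble(
    quadrant = as.integer(substr(code, 1L, 1L)),
    position = as.integer(substr(code, 2L, 2L))
  )
}

# Normalise a dialect spec: NULL, a named list, or a path to a YAML/JSON file
# with optional entries `rename` (canonical = file column) and `fdi_tooth`
# (name of a two-digit FDI tooth column replacing quadrant/tooth).
as_dialect <- function(dialect) {
  if (is.null(dialect)) {
    return(list(rename = NULL, fdi_tooth = NULL))
  }
  if (is.character(dialect) && length(dialect) == 1L) {
    if (!file.exists(dialect)) {
      abort(sprintf("Dialect file not found: %s", dialect),
            class = "consistr_io_error")
    }
    dialect <- if (grepl("\\.json$", dialect, ignore.case = TRUE)) {
      jsonlite::read_json(dialect, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(dialect)
    }
  }
  if (!is.list(dialect)) {
    abort("`dialect` must be NULL, a list, or a file path.",
          class = "consistr_config_error")
  }
  unknown <- setdiff(names(dialect), c("rename", "fdi_tooth"))
  if (length(unknown)) {
    abort(sprintf("Unknown dialect field(s): %s",
                  paste(unknown, collapse = ", ")),
          class = "consistr_config_error")
  }
  list(rename = dialect$rename, fdi_tooth = dialect$fdi_tooth)
}

#' Read and validate observation-level assessment records
#'
#' Reads the canonical per-stage CSV (see [observation_schema()]), optionally
#' translating a non-canonical layout via `dialect`, coerces column types and
#' validates every row against the domain invariants. Invalid rows are
#' reported by row number; nothing is silently dropped.
#'
#' A missing `material` column is filled with `NA`; a missing
#' `staff_difficult_flag` column is interpreted as all-`false` (the flag
#' marks exceptional added difficulty). An optional integer `stage_index`
#' column, if present, is retained and later used to order stages.
#'
#' @param path Path to a CSV file.
#' @param dialect Optional schema dialect: a list (or path to a YAML/JSON
#'   file) with entries `rename` (named list mapping canonical column name to
#'   the column name used in the file) and/or `fdi_tooth` (name of a column
#'   holding two-digit FDI tooth codes in place of `quadrant`/`tooth`).
#' @return A validated tibble of observations, one row per stage judgement.
#' @export
read_observations <- function(path, dialect = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("No such file: %s", path), class = "consistr_io_error")
  }
  dl <- as_dialect(dialect)
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (!is.null(dl$rename)) {
    for (canon in names(dl$rename)) {
      from <- dl$rename[[canon]]
      if (!from %in% names(raw)) {
        abort(sprintf("Dialect renames '%s' from missing column '%s'.",
                      canon, from),
              class = "consistr_schema_error")
      }
      names(raw)[names(raw) == from] <- canon
    }
  }
  if (!is.null(dl$fdi_tooth)) {
    if (!dl$fdi_tooth %in% names(raw)) {
      abort(sprintf("FDI tooth column '%s' not found.", dl$fdi_tooth),
            class = "consistr_schema_error")
    }
    site <- parse_fdi_tooth(raw[[dl$fdi_tooth]])
    raw$quadrant <- as.character(site$quadrant)
    raw$tooth <- as.character(site$position)
    raw[[dl$fdi_tooth]] <- NULL
  }
  required <- setdiff(observation_schema(), c("material", "staff_difficult_flag"))
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    abort(c("CSV is missing required column(s):", missing),
          class = "consistr_schema_error")
  }
  if (!"material" %in% names(raw)) raw$material <- NA_character_
  if (!"staff_difficult_flag" %in% names(raw)) raw$staff_difficult_flag <- "false"
  validate_observations(coerce_observations(raw))
}

# Coerce character columns to their domain types; unparseable values become
# NA here and are reported, with row numbers, by validate_observations().
coerce_observations <- function(raw) {
  to_int <- function(x) suppressWarnings(as.integer(x))
  flag_raw <- tolower(trimws(as.character(raw$staff_difficult_flag)))
  flag <- rep(NA, nrow(raw))
  flag[flag_raw %in% c("true", "t", "1", "yes")] <- TRUE
  flag[flag_raw %in% c("false", "f", "0", "no", "", NA) |
         is.na(flag_raw)] <- FALSE
  out <- tibble(
    student_id = as.character(raw$student_id),
    cohort_id = as.character(raw$cohort_id),
    year_of_study = to_int(raw$year_of_study),
    staff_id = as.character(raw$staff_id),
    patient_id = as.character(raw$patient_id),
    restoration_id = as.character(raw$restoration_id),
    stage_id = as.character(raw$stage_id),
    di = to_int(raw$di),
    quadrant = to_int(raw$quadrant),
    tooth = to_int(raw$tooth),
    surface = as.character(raw$surface),
    material = as.character(raw$material),
    staff_difficult_flag = as.logical(flag)
  )
  if ("stage_index" %in% names(raw)) {
    out$stage_index <- to_int(raw$stage_index)
  }
  out
}

#' Validate a tibble of observations
#'
#' Checks every row against the domain invariants: DI in 1-6, quadrant 1-4,
#' tooth position 1-8, a known surface class, year of study in 3-5, and
#' non-missing identifiers. On failure, an error of class
#' `consistr_validation_error` lists the offending rows (row numbers refer to
#' data rows, excluding the header).
#'
#' @param obs A tibble with the columns of [observation_schema()].
#' @return `obs`, invisibly unchanged, if valid.
#' @export
validate_observations <- function(obs) {
  obs <- as_tibble(obs)
  missing <- setdiff(setdiff(observation_schema(), "material"), names(obs))
  if (length(missing)) {
    abort(c("Observations are missing column(s):", missing),
          class = "consistr_schema_error")
  }
  if (!"material" %in% names(obs)) obs$material <- NA_character_
  problems <- character()
  note <- function(bad, fmt, values) {
    if (any(bad)) {
      rows <- which(bad)
      problems <<- c(
        problems,
        utils::head(sprintf(fmt, rows, as.character(values[rows])), 20L)
      )
    }
  }
  ids <- c("student_id", "cohort_id", "staff_id", "patient_id",
           "restoration_id", "stage_id")
  for (col in ids) {
    note(is.na(obs[[col]]) | obs[[col]] == "",
         paste0("row %s: missing ", col, " ('%s')"), obs[[col]])
  }
  note(!(obs$di %in% 1:6), "row %s: di '%s' outside 1-6", obs$di)
  note(!(obs$year_of_study %in% 3:5),
       "row %s: year_of_study '%s' outside 3-5", obs$year_of_study)
  note(!(obs$quadrant %in% 1:4), "row %s: quadrant '%s' outside 1-4",
       obs$quadrant)
  note(!(obs$tooth %in% 1:8), "row %s: tooth position '%s' outside 1-8",
       obs$tooth)
  note(!(obs$surface %in% surface_classes()),
       "row %s: unknown surface class '%s'", obs$surface)
  note(is.na(obs$staff_difficult_flag),
       "row %s: staff_difficult_flag '%s' not true/false",
       obs$staff_difficult_flag)
  if (length(problems)) {
    abort(c(sprintf("%d invalid observation row(s):", length(problems)),
            problems),
          class = "consistr_validation_error")
  }
  obs
}

#' Write observations to the canonical CSV
#'
#' Inverse of [read_observations()]: booleans are serialised as
#' `true`/`false` and columns are emitted in schema order (plus
#' `stage_index` when present). Reading the file back yields an identical
#' record set.
#'
#' @param obs A validated observations tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(obs, path) {
  obs <- validate_observations(obs)
  cols <- c(observation_schema(),
            if ("stage_index" %in% names(obs)) "stage_index")
  out <- obs[, cols]
  out$staff_difficult_flag <- ifelse(out$staff_difficult_flag, "true", "false")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Assemble stage observations into restoration-level records
#'
#' Groups validated observations by `restoration_id` into one record per
#' restoration, carrying the shared context (student, cohort, year, staff,
#' patient, tooth site, surface, difficulty flag), the ordered stage DI
#' scores and their minimum. Stages are ordered by `stage_index` when that
#' column is present, otherwise lexicographically by `stage_id`; only the
#' minimum is used downstream, so the ordering never changes results.
#'
#' Context fields must be constant within a restoration (each restoration is
#' observed by a single staff member on each occasion); a conflict raises an
#' error of class `consistr_integrity_error` naming the restoration.
#'
#' @param obs A validated observations tibble.
#' @param keep_stages Keep the per-stage DI vectors as a `stage_dis` list
#'   column? Disable for large simulated cohorts where only `min_di` is
#'   needed.
#' @return A tibble with one row per restoration: context columns,
#'   `n_stages`, `min_di` and (optionally) `stage_dis`.
#' @export
assemble_restorations <- function(obs, keep_stages = TRUE) {
  obs <- validate_observations(obs)
  context <- c("student_id", "cohort_id", "year_of_study", "staff_id",
               "patient_id", "quadrant", "tooth", "surface",
               "staff_difficult_flag")
  # integrity: every restoration_id must map to a single context combination
  uniq <- obs$restoration_id[!duplicated(obs[, c("restoration_id", context)])]
  conflicted <- unique(uniq[duplicated(uniq)])
  if (length(conflicted)) {
    abort(
      c("Conflicting context fields within restoration_id(s):",
        utils::head(conflicted, 5L)),
      class = "consistr_integrity_error"
    )
  }
  key <- if ("stage_index" %in% names(obs)) obs$stage_index else obs$stage_id
  obs <- obs[order(obs$restoration_id, key), ]
  firsts <- !duplicated(obs$restoration_id)
  gidx <- cumsum(firsts)
  res <- obs[firsts, c("restoration_id", context)]
  res$n_stages <- tabulate(gidx)
  # min per contiguous group: sort stage DIs within group, take the first
  by_min <- order(gidx, obs$di)
  res$min_di <- obs$di[by_min][firsts]
  if (keep_stages) {
    res$stage_dis <- split(obs$di, gidx)
    names(res$stage_dis) <- NULL
  }
  as_tibble(res)
}
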