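# Case-difficulty rule and per-student difficulty exposure.

#' Classify restorations as relatively difficult
#'
#' A restoration is difficult if any of three clauses fires:
#' it is approximal (either approximal surface class), it is on an upper
#' posterior tooth (FDI quadrant 1 or 2, positions 4-8), or supervising
#' staff tagged it as difficult for another reason (e.g. poor patient
#' cooperation). The rule is binary; a restoration satisfying several
#' clauses is still counted once.
#'
#' @param restorations A restorations tibble from [assemble_restorations()].
#' @return Logical vector, one element per restoration.
#' @export
is_difficult <- function(restorations) {
  is_approximal(restorations$surface) |
    is_upper_posterior(restorations$quadrant, restorations$tooth) |
    restorations$staff_difficult_flag
}

#' Per-student difficulty exposure
#'
#' Counts each student's difficult restorations and expresses them as a
#' percentage of the total restorations placed.
#'
#' @inheritParams is_difficult
#' @return A tibble with columns `student_id`, `cohort_id`, `n_total`,
#'   `n_difficult`, `pct_difficult` (0-100).
#' @export
difficulty_summary <- function(restorations) {
  if (nrow(restorations) == 0L) {
    abort("Difficulty exposure is undefined for an empty set of restorations.",
          class = "consistr_empty_error")
  }
  restorations |>
    mutate(.diff = is_difficult(restorations)) |>
    group_by(.data$student_id, .data$cohort_id) |>
    summarise(
      n_total = n(),
      n_difficult = sum(.data$.diff),
      pct_difficult = 100 * .data$n_difficult / .data$n_total,
      .groups = "drop"
    ) |>
    arrange(.data$student_id)
}
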