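#' Area under a predicted response curve
#'
#' Trapezoidal integral of the predicted response probability over the
#' frequency grid for one note variant; units kHz x probability. This is
#' an integral of a response curve, not a classifier ROC area.
#'
#' @param curves a `"response_curves"` object from [predict_curves()], or
#'   a list with `grid` and `prob`.
#' @param note note level to integrate (must be among the fitted levels).
#' @return the area (non-negative number).
#' @export
curve_auc <- function(curves, note) {
  g <- curves$grid
  if (length(g) < 2L) stop("grid needs at least 2 points")
  if (is.unsorted(g, strictly = TRUE)) stop("frequency grid must be sorted")
  j <- match(note, curves$note_levels)
  if (is.na(j)) stop("note level ", note, " not among fitted curves")
  p <- curves$prob[, j]
  sum(diff(g) * (p[-1L] + p[-length(p)]) / 2)
}

#' Relative response of each note variant
#'
#' The study's headline per-population statistic: the AUC of each note
#' variant's predicted response curve expressed as a proportion of the AUC
#' for the population's own variant. The own variant is exactly 1 by
#' construction; values above 1 mean a foreign (e.g. ancestral) variant
#' elicits a stronger response than the population's own call.
#'
#' @param curves a `"response_curves"` object.
#' @param own_note the population's own note count (must be a fitted
#'   level with positive AUC).
#' @return an object of class `"relative_response"`: data.frame with
#'   columns `note`, `auc`, `relative` and attributes `own_note`,
#'   `population`.
#' @export
relative_response_table <- function(curves, own_note) {
  if (!(own_note %in% curves$note_levels))
    stop("own_note ", own_note, " was not a tested variant")
  auc <- vapply(curves$note_levels, function(l) curve_auc(curves, l), 0)
  own <- auc[match(own_note, curves$note_levels)]
  if (own <= 0)
    stop("own-call AUC is zero; relative response undefined")
  out <- data.frame(note = curves$note_levels, auc = auc,
                    relative = auc / own)
  attr(out, "own_note") <- own_note
  attr(out, "population") <- curves$population
  class(out) <- c("relative_response", "data.frame")
  out
}

#' Classify a population into the three recognition scenarios
#'
#' * **null** — the population responds alike to all note variants (no
#'   significant note effect).
#' * **matched** — matched-spaces: only the own variant is recognized
#'   (significant note effect and every non-own relative response at or
#'   below `floor`).
#' * **intermediate** — a significant note effect with partial recognition
#'   of non-own variants.
#'
#' @param rel_table a `"relative_response"` table.
#' @param note_p p-value of the note-effect likelihood-ratio test.
#' @param alpha significance level (use [bonferroni_threshold()] for the
#'   corrected 0.00625).
#' @param floor relative response at or below which a variant counts as
#'   not recognized (default 0.05).
#' @return an object of class `"scenario_call"`: list with `population`,
#'   `scenario`, `note_p`, `min_relative`, `max_relative`, `own_note`.
#' @export
classify_scenario <- function(rel_table, note_p, alpha = 0.05,
                              floor = 0.05) {
  own <- attr(rel_table, "own_note")
  non_own <- rel_table$relative[rel_table$note != own]
  scenario <- if (is.na(note_p) || note_p >= alpha) {
    "null"
  } else if (length(non_own) && all(non_own <= floor)) {
    "matched"
  } else {
    "intermediate"
  }
  out <- list(population = attr(rel_table, "population"),
              scenario = scenario, note_p = note_p,
              min_relative = min(rel_table$relative),
              max_relative = max(rel_table$relative),
              own_note = own)
  class(out) <- "scenario_call"
  out
}

#' @export
print.scenario_call <- function(x, ...) {
  cat(sprintf("%s: %s (own note %d, note-effect p = %.4g, relative range [%.3g, %.3g])\n",
              x$population, x$scenario, x$own_note, x$note_p,
              x$min_relative, x$max_relative))
  invisible(x)
}
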