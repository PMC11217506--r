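#' Background-correct an average radiance
#'
#' Subtracts the background-well radiance (an empty well imaged alongside
#' the excised lymph nodes) from a region-of-interest average radiance.
#' Instruments can read below background, so negative differences are
#' clamped to zero and flagged rather than propagated: a zero corrected
#' signal makes a downstream fold change unevaluable, never silently
#' infinite.
#'
#' @param radiance,background Non-negative average radiances (p/s/cm2/sr).
#' @return A tibble `corrected`, `clamped` (TRUE where the correction hit
#'   zero).
#' @export
background_correct <- function(radiance, background) {
  if (any(radiance < 0, na.rm = TRUE) || any(background < 0, na.rm = TRUE)) {
    stop("radiance and background must be non-negative", call. = FALSE)
  }
  corrected <- pmax(radiance - background, 0)
  tibble::tibble(corrected = corrected, clamped = corrected == 0)
}

#' Draining / contralateral fold change for one mouse
#'
#' Selects the draining lymph node with the highest background-corrected
#' signal and divides it by the corrected signal of the contralateral node
#' at the same anatomical station. A zero contralateral signal leaves the
#' fold change undefined (`NA`) — the mouse is unevaluable.
#'
#' @param records A bioluminescence tibble for one mouse: columns
#'   `station`, `side` ("draining"/"contralateral"), `radiance`,
#'   `background`.
#' @return A one-row tibble: `fold`, `station_used`.
#' @export
dln_fold_change <- function(records) {
  corr <- background_correct(records$radiance, records$background)
  records$corrected <- corr$corrected
  dln <- records[records$side == "draining", , drop = FALSE]
  ndln <- records[records$side == "contralateral", , drop = FALSE]
  if (nrow(dln) == 0) stop("no draining-node records", call. = FALSE)
  best <- dln[which.max(dln$corrected), , drop = FALSE]
  match_c <- ndln$corrected[ndln$station == best$station]
  if (length(match_c) == 0) {
    stop(sprintf("no contralateral record at station '%s'", best$station),
         call. = FALSE)
  }
  fold <- if (match_c[1] <= 0) NA_real_ else best$corrected / match_c[1]
  tibble::tibble(fold = fold, station_used = best$station)
}

#' Metastasis positivity call
#'
#' A lymph node is called tumor-cell positive when its draining /
#' contralateral fold change exceeds the cutoff (strictly). The default
#' cutoff of 4 encodes a 300% signal increase over the non-draining node:
#' a 300% increase means 1 + 300/100 = 4 times the signal.
#'
#' @param fold Non-negative fold changes (`NA` = unevaluable).
#' @param cutoff Positivity cutoff (default 4).
#' @return Logical vector (`NA` propagates).
#' @export
classify_positivity <- function(fold, cutoff = 4) {
  stopifnot(all(fold >= 0, na.rm = TRUE), cutoff > 0)
  fold > cutoff
}

#' Cohort DLN positivity table
#'
#' Per-mouse fold changes and positivity calls plus the group rate
#' (positives over evaluable mice).
#'
#' @param records A bioluminescence tibble (multiple mice), columns
#'   `mouse_id`, `station`, `side`, `radiance`, `background`.
#' @param cutoff Positivity cutoff (default 4).
#' @return A list with `per_mouse` (tibble `mouse_id`, `fold`,
#'   `station_used`, `positive`) and `rate` (tibble `n_positive`,
#'   `n_evaluable`, `rate_pct`).
#' @export
cohort_positivity <- function(records, cutoff = 4) {
  per_mouse <- records |>
    dplyr::group_by(.data$mouse_id) |>
    dplyr::group_modify(~ dln_fold_change(.x)) |>
    dplyr::ungroup() |>
    dplyr::mutate(positive = classify_positivity(.data$fold, cutoff))
  evaluable <- !is.na(per_mouse$positive)
  rate <- tibble::tibble(
    n_positive = sum(per_mouse$positive[evaluable]),
    n_evaluable = sum(evaluable),
    rate_pct = 100 * sum(per_mouse$positive[evaluable]) /
      max(sum(evaluable), 1L)
  )
  list(per_mouse = per_mouse, rate = rate)
}
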