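#' Metric normalization rules
#'
#' The small arithmetic normalizations applied to flow-cytometry, cytokine,
#' qPCR and transwell-migration summaries before group comparison. All are
#' vectorized.
#'
#' \describe{
#'   \item{`absolute_count(pct_total, total_cells)`}{population "% of
#'     Total" times the absolute cell count of the sample.}
#'   \item{`per_mg(count, mass_mg)`}{cell count per milligram of tumor.}
#'   \item{`normalize_to_control(value, control_values)`}{percent of the
#'     control-group mean; by design the control group itself averages to
#'     exactly 100.}
#'   \item{`isotype_corrected_mfi(mfi, isotype_mfi)`}{isotype-control MFI
#'     subtracted from the stained MFI. Negative results are kept (with a
#'     flag), not clamped: clamping would bias group means upward.}
#'   \item{`migration_index(migrated, baseline_migrated)`}{migrated-cell
#'     count over the basal (serum-attractant) migration count.}
#'   \item{`reference_gene_ratio(target_quantity, reference_quantity)`}{
#'     target transcript quantity over the reference-gene quantity.}
#' }
#'
#' @param pct_total Percent of total cells, in \[0, 100\].
#' @param total_cells,count,mass_mg,value,mfi,isotype_mfi Non-negative
#'   numerics as named.
#' @param control_values Numeric vector of control-sample values (positive
#'   mean required).
#' @param migrated,baseline_migrated Migrated-cell counts (baseline > 0).
#' @param target_quantity,reference_quantity Transcript quantities
#'   (reference > 0).
#' @name normalization
NULL

#' @rdname normalization
#' @export
absolute_count <- function(pct_total, total_cells) {
  if (any(pct_total < 0 | pct_total > 100, na.rm = TRUE)) {
    stop("`pct_total` must be within [0, 100]", call. = FALSE)
  }
  if (any(total_cells < 0, na.rm = TRUE)) {
    stop("`total_cells` must be non-negative", call. = FALSE)
  }
  pct_total / 100 * total_cells
}

#' @rdname normalization
#' @export
per_mg <- function(count, mass_mg) {
  if (any(mass_mg <= 0, na.rm = TRUE)) {
    stop("`mass_mg` must be positive", call. = FALSE)
  }
  count / mass_mg
}

#' @rdname normalization
#' @export
normalize_to_control <- function(value, control_values) {
  control_values <- control_values[!is.na(control_values)]
  if (length(control_values) == 0) {
    stop("control set is empty", call. = FALSE)
  }
  ctrl_mean <- mean(control_values)
  if (ctrl_mean <= 0) stop("control mean must be positive", call. = FALSE)
  100 * value / ctrl_mean
}

#' @rdname normalization
#' @export
isotype_corrected_mfi <- function(mfi, isotype_mfi) {
  if (any(mfi < 0 | isotype_mfi < 0, na.rm = TRUE)) {
    stop("MFI values must be non-negative", call. = FALSE)
  }
  corrected <- mfi - isotype_mfi
  tibble::tibble(corrected = corrected, below_isotype = corrected < 0)
}

#' @rdname normalization
#' @export
migration_index <- function(migrated, baseline_migrated) {
  if (any(baseline_migrated <= 0, na.rm = TRUE)) {
    stop("`baseline_migrated` must be positive", call. = FALSE)
  }
  migrated / baseline_migrated
}

#' @rdname normalization
#' @export
reference_gene_ratio <- function(target_quantity, reference_quantity) {
  if (any(reference_quantity <= 0, na.rm = TRUE)) {
    stop("`reference_quantity` must be positive", call. = FALSE)
  }
  target_quantity / reference_quantity
}

#' Normalize a long metric table to its control group
#'
#' Applies [normalize_to_control()] within each `(experiment_id,
#' metric_name)` batch: every value becomes a percent of that experiment's
#' control-group mean. Normalizing within experiment absorbs batch effects
#' between independent experiments.
#'
#' @param metrics A tibble with columns `mouse_id`, `group`, `metric_name`,
#'   `value` and optionally `experiment_id` (a single batch is assumed when
#'   absent).
#' @param control_group Label of the control group.
#' @return The input tibble with a `normalized_value` column (percent of
#'   control mean).
#' @export
normalize_metrics <- function(metrics, control_group) {
  if (!"experiment_id" %in% names(metrics)) metrics$experiment_id <- "exp1"
  if (!control_group %in% metrics$group) {
    stop(sprintf("control group '%s' not present", control_group),
         call. = FALSE)
  }
  metrics |>
    dplyr::group_by(.data$experiment_id, .data$metric_name) |>
    dplyr::mutate(normalized_value = normalize_to_control(
      .data$value, .data$value[.data$group == control_group])) |>
    dplyr::ungroup()
}
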