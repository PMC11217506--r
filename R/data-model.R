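#' Caliper tumor volume
#'
#' Converts paired caliper readings into a tumor volume with the standard
#' ellipsoid approximation \eqn{V = L \cdot W^2 / 2}, where `L` is the largest
#' diameter and `W` the diameter perpendicular to it, both in millimetres.
#'
#' @param length_mm Numeric vector, largest tumor diameter (mm).
#' @param width_mm Numeric vector, perpendicular diameter (mm). Must satisfy
#'   `0 < width_mm <= length_mm` elementwise; a width exceeding the length
#'   indicates swapped calipers and is an error, never silently corrected.
#' @return Numeric vector of tumor volumes in cubic millimetres.
#' @examples
#' caliper_volume(10, 6) # 180
#' @export
caliper_volume <- function(length_mm, width_mm) {
  if (!is.numeric(length_mm) || !is.numeric(width_mm)) {
    stop("`length_mm` and `width_mm` must be numeric", call. = FALSE)
  }
  bad <- !is.na(length_mm) & !is.na(width_mm)
  if (any(bad & (length_mm <= 0 | width_mm <= 0))) {
    stop("caliper dimensions must be positive", call. = FALSE)
  }
  if (any(bad & width_mm > length_mm)) {
    stop("`width_mm` exceeds `length_mm`; dimensions are likely swapped",
         call. = FALSE)
  }
  length_mm * width_mm^2 / 2
}

measurement_cols <- c("mouse_id", "group", "tumor_site", "day",
                      "length_mm", "width_mm", "volume_mm3")

#' Read a long-format caliper measurement table
#'
#' Reads a comma-separated measurement table with one row per mouse, day and
#' tumor site. Volumes are taken from `volume_mm3` when present and otherwise
#' computed from `length_mm`/`width_mm` via [caliper_volume()]. Days are
#' integers relative to the day of tumor irradiation (day 0); negative days
#' denote pre-treatment measurements.
#'
#' Required columns: `mouse_id`, `group`, `tumor_site`, `day`, and either
#' `volume_mm3` or both `length_mm` and `width_mm` (the dimension columns may
#' be absent entirely). Duplicate `(mouse_id, tumor_site, day)` rows are a
#' hard error: averaging duplicates would hide upstream data faults.
#'
#' @param path Path to a CSV file (UTF-8, header row, decimal point).
#' @return A tibble of validated measurements with all seven canonical
#'   columns (`length_mm`/`width_mm` are `NA` where only volumes were given).
#' @export
read_measurements <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_measurements(raw, context = path)
}

#' Validate an in-memory measurement table
#'
#' Applies the same checks as [read_measurements()] to a data frame that was
#' built in code: column presence, positivity, the length >= width contract,
#' volume completion from calipers, and duplicate-key rejection.
#'
#' @param x A data frame of measurements.
#' @param context Label used in error messages (defaults to the expression).
#' @return A validated measurement tibble.
#' @export
validate_measurements <- function(x, context = deparse(substitute(x))) {
  x <- tibble::as_tibble(x)
  if (!"length_mm" %in% names(x)) x$length_mm <- NA_real_
  if (!"width_mm" %in% names(x)) x$width_mm <- NA_real_
  if (!"volume_mm3" %in% names(x)) x$volume_mm3 <- NA_real_
  if (!"tumor_site" %in% names(x)) x$tumor_site <- "primary"
  missing_cols <- setdiff(measurement_cols, names(x))
  if (length(missing_cols) > 0) {
    stop(sprintf("%s: missing required column(s): %s", context,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (!all(x$tumor_site %in% c("primary", "secondary"))) {
    stop(sprintf("%s: tumor_site must be 'primary' or 'secondary'", context),
         call. = FALSE)
  }
  if (any(is.na(x$day)) || any(x$day != round(x$day))) {
    stop(sprintf("%s: `day` must be integer-valued", context), call. = FALSE)
  }
  x$day <- as.integer(x$day)

  no_volume <- is.na(x$volume_mm3)
  derivable <- no_volume & !is.na(x$length_mm) & !is.na(x$width_mm)
  if (any(no_volume & !derivable)) {
    bad <- which(no_volume & !derivable)[1]
    stop(sprintf("%s: row %d has neither volume_mm3 nor a length/width pair",
                 context, bad), call. = FALSE)
  }
  if (any(derivable)) {
    x$volume_mm3[derivable] <- caliper_volume(x$length_mm[derivable],
                                              x$width_mm[derivable])
  }
  if (any(x$volume_mm3 <= 0)) {
    stop(sprintf("%s: volumes must be positive", context), call. = FALSE)
  }
  key <- paste(x$mouse_id, x$tumor_site, x$day, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))[1]
    stop(sprintf(
      "%s: duplicate measurement for mouse '%s', site '%s', day %d (row %d)",
      context, x$mouse_id[dup], x$tumor_site[dup], x$day[dup], dup),
      call. = FALSE)
  }
  dplyr::select(x, dplyr::all_of(measurement_cols))
}

#' Write a measurement table
#'
#' Writes the canonical comma-separated dialect read by
#' [read_measurements()]; a write/read round trip is value-identical.
#'
#' @param measurements A measurement tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(measurements, path) {
  readr::write_csv(measurements, path, progress = FALSE)
  invisible(path)
}

#' Assemble per-mouse growth curves
#'
#' Groups a validated measurement table into one growth curve per
#' `(mouse_id, tumor_site)`, each a time-sorted `(day, volume_mm3)` series
#' with its day-0 anchor volume `v_start`. When no day-0 measurement exists,
#' the nearest measurement in the window \[-2, 0\] serves as the anchor
#' (measurement schedules are not guaranteed to hit the irradiation day
#' exactly); a mouse with no usable anchor, or with fewer than two
#' measurements, is kept with `exit_reason = "excluded"` rather than
#' silently dropped.
#'
#' @param measurements A measurement tibble (see [read_measurements()]).
#' @param followup_end Last study day (integer). Curves whose last
#'   measurement reaches this day get `exit_reason = "study_end"`, earlier
#'   exits get `"endpoint_reached"` unless the table carries an
#'   `exit_reason` column of its own (as the simulator's tables do).
#' @return A tibble with one row per curve: `mouse_id`, `group`,
#'   `tumor_site`, `v_start`, `followup_end`, `exit_reason`, and a
#'   `measurements` list-column of `(day, volume_mm3)` tibbles.
#' @export
build_curves <- function(measurements, followup_end = NULL) {
  measurements <- validate_measurements(measurements,
                                        context = "build_curves input")
  if (is.null(followup_end)) followup_end <- max(measurements$day)
  has_exit <- "exit_reason" %in% names(measurements)

  curves <- measurements |>
    dplyr::select(dplyr::all_of(c("mouse_id", "group", "tumor_site",
                                  "day", "volume_mm3"))) |>
    dplyr::arrange(.data$mouse_id, .data$tumor_site, .data$day) |>
    tidyr::nest(measurements = c("day", "volume_mm3"))

  curves$v_start <- purrr::map_dbl(curves$measurements, anchor_volume)
  curves$followup_end <- as.integer(followup_end)
  last_day <- purrr::map_int(curves$measurements, ~ max(.x$day))
  n_meas <- purrr::map_int(curves$measurements, nrow)
  curves$exit_reason <- dplyr::case_when(
    n_meas < 2 | is.na(curves$v_start) ~ "excluded",
    last_day >= followup_end ~ "study_end",
    TRUE ~ "endpoint_reached"
  )
  curves
}

# Day-0 anchor, falling back to the nearest measurement in [-2, 0].
anchor_volume <- function(m) {
  eligible <- m$day >= -2L & m$day <= 0L
  if (!any(eligible)) return(NA_real_)
  m$volume_mm3[eligible][which.max(m$day[eligible])]
}

# Shared helper: pull one curve (a one-row tibble or a list with
# measurements/v_start) into a plain list used by the scoring engines.
as_curve <- function(curve) {
  if (is.data.frame(curve) && "measurements" %in% names(curve)) {
    stopifnot(nrow(curve) == 1)
    list(
      mouse_id = curve$mouse_id[[1]],
      group = if ("group" %in% names(curve)) curve$group[[1]] else NA_character_,
      tumor_site = if ("tumor_site" %in% names(curve)) curve$tumor_site[[1]] else "primary",
      measurements = curve$measurements[[1]],
      v_start = if ("v_start" %in% names(curve)) curve$v_start[[1]] else NA_real_,
      followup_end = if ("followup_end" %in% names(curve)) curve$followup_end[[1]] else max(curve$measurements[[1]]$day),
      exit_reason = if ("exit_reason" %in% names(curve)) curve$exit_reason[[1]] else "study_end"
    )
  } else if (is.list(curve) && !is.null(curve$measurements)) {
    curve
  } else {
    stop("not a growth curve", call. = FALSE)
  }
}
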