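#' Per-day percent volume change and its running average
#'
#' For one growth curve, computes at every measured post-treatment day `d`
#' the percent volume change relative to the day-0 anchor,
#' \deqn{\Delta V_d = 100 (V_d - V_{start}) / V_{start},}
#' and the running average \eqn{\bar{\Delta V}_d}, the mean of
#' \eqn{\Delta V} over all measured days in \[0, d\]. The running average
#' uses a count-based mean so it stays well defined on irregular measurement
#' schedules (dividing the running sum by the day index `d` instead is
#' available via `denominator = "day"`, but is undefined at day 0 and skewed
#' whenever sampling is not daily).
#'
#' @param curve A one-row curve tibble (see [build_curves()]) or an
#'   equivalent list.
#' @param denominator `"count"` (default) or `"day"`.
#' @return A tibble with columns `day`, `delta_v`, `delta_v_bar`, restricted
#'   to measured days >= 0; zero rows (with attribute `unevaluable = TRUE`)
#'   when the curve has no day-0 anchor or no post-treatment measurement.
#' @export
volume_change_series <- function(curve, denominator = c("count", "day")) {
  denominator <- match.arg(denominator)
  cv <- as_curve(curve)
  m <- cv$measurements[cv$measurements$day >= 0, , drop = FALSE]
  if (is.na(cv$v_start) || cv$v_start <= 0 || nrow(m) == 0) {
    out <- tibble::tibble(day = integer(), delta_v = numeric(),
                          delta_v_bar = numeric())
    attr(out, "unevaluable") <- TRUE
    return(out)
  }
  delta_v <- 100 * (m$volume_mm3 - cv$v_start) / cv$v_start
  delta_v_bar <- switch(denominator,
    count = cumsum(delta_v) / seq_along(delta_v),
    day = ifelse(m$day == 0, delta_v, cumsum(delta_v) / m$day)
  )
  tibble::tibble(day = m$day, delta_v = delta_v, delta_v_bar = delta_v_bar)
}

#' Best response and best average response
#'
#' `best_response()` is the minimum percent volume change over measured days
#' at or after `min_day`; `best_average_response()` is the same minimum
#' applied to the running-average series. Both return `NA` (unevaluable)
#' when no measurement at `day >= min_day` exists — a mouse lost before the
#' evaluation window cannot be scored.
#'
#' @param series A change series from [volume_change_series()].
#' @param min_day First day eligible for the minimum (default 7).
#' @return A single number, or `NA_real_` if unevaluable.
#' @export
best_response <- function(series, min_day = 7) {
  eligible <- series$delta_v[series$day >= min_day]
  if (length(eligible) == 0) return(NA_real_)
  min(eligible)
}

#' @rdname best_response
#' @export
best_average_response <- function(series, min_day = 7) {
  eligible <- series$delta_v_bar[series$day >= min_day]
  if (length(eligible) == 0) return(NA_real_)
  min(eligible)
}

#' mRECIST response call
#'
#' Classifies a (BR, BAR) pair into the murine RECIST categories with
#' strict inequalities, evaluated in precedence order:
#' \itemize{
#'   \item mCR (complete response): BR < -95 and BAR < -40
#'   \item mPR (partial response): BR < -50 and BAR < -20
#'   \item mSD (stable disease): BR < 35 and BAR < 30
#'   \item mPD (progressive disease): not otherwise categorized
#' }
#' The threshold sets overlap, so order matters: a pair is assigned the
#' first category whose both conditions hold. Exactly (-95, -40) fails the
#' strict mCR thresholds but satisfies mPR. `NA` in either input propagates
#' to `"unevaluable"`.
#'
#' @param br,bar Numeric vectors of best response / best average response
#'   (percent).
#' @return A character vector over
#'   `c("mCR", "mPR", "mSD", "mPD", "unevaluable")`.
#' @export
classify_response <- function(br, bar) {
  dplyr::case_when(
    is.na(br) | is.na(bar) ~ "unevaluable",
    br < -95 & bar < -40 ~ "mCR",
    br < -50 & bar < -20 ~ "mPR",
    br < 35 & bar < 30 ~ "mSD",
    TRUE ~ "mPD"
  )
}

mrecist_levels <- c("mCR", "mPR", "mSD", "mPD", "unevaluable")

#' Score a cohort of growth curves by mRECIST
#'
#' Computes BR, BAR and the response call for every curve. Curves with no
#' usable day-0 anchor or no measurement at `day >= min_day` are kept as
#' `"unevaluable"` rather than dropped.
#'
#' @param curves A curve tibble from [build_curves()] or
#'   [simulate_cohort()].
#' @param min_day First day eligible for BR/BAR (default 7).
#' @param denominator Running-average convention, see
#'   [volume_change_series()].
#' @return A `mrecist_result` tibble: `mouse_id`, `group`, `br`, `bar`,
#'   `call` (factor over mCR/mPR/mSD/mPD/unevaluable).
#' @export
mrecist_score <- function(curves, min_day = 7,
                          denominator = c("count", "day")) {
  denominator <- match.arg(denominator)
  primary <- if ("tumor_site" %in% names(curves)) {
    curves[curves$tumor_site == "primary", , drop = FALSE]
  } else {
    curves
  }
  res <- purrr::map_dfr(seq_len(nrow(primary)), function(i) {
    row <- primary[i, , drop = FALSE]
    ser <- volume_change_series(row, denominator = denominator)
    tibble::tibble(
      mouse_id = row$mouse_id,
      group = if ("group" %in% names(row)) row$group else NA_character_,
      br = best_response(ser, min_day),
      bar = best_average_response(ser, min_day)
    )
  })
  if (nrow(res) == 0) {
    res <- tibble::tibble(mouse_id = character(), group = character(),
                          br = numeric(), bar = numeric())
  }
  res$call <- factor(classify_response(res$br, res$bar),
                     levels = mrecist_levels)
  class(res) <- c("mrecist_result", class(res))
  res
}

#' Waterfall table of best average responses
#'
#' One row per mouse, sorted by BAR descending — the order in which
#' waterfall plots are drawn, progressive disease on the left, complete
#' responses on the right.
#'
#' @param x A curve tibble or an existing `mrecist_result`.
#' @param ... Passed to [mrecist_score()] when `x` is a curve tibble.
#' @return A `mrecist_result` tibble in waterfall order.
#' @export
cohort_waterfall <- function(x, ...) {
  scores <- if (inherits(x, "mrecist_result")) x else mrecist_score(x, ...)
  out <- dplyr::arrange(scores, dplyr::desc(.data$bar))
  class(out) <- unique(c("mrecist_result", class(out)))
  out
}

#' Per-group mRECIST response rates
#'
#' @param scores A `mrecist_result` tibble.
#' @return A tibble with one row per group and response category:
#'   `group`, `call`, `n`, `n_evaluable`, `rate_pct` (percent of evaluable
#'   mice in the group).
#' @export
mrecist_rates <- function(scores) {
  scores |>
    dplyr::count(.data$group, .data$call, .drop = FALSE) |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(n_evaluable = sum(.data$n[.data$call != "unevaluable"])) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$call != "unevaluable" | .data$n > 0) |>
    dplyr::mutate(rate_pct = ifelse(
      .data$call == "unevaluable", NA_real_,
      100 * .data$n / pmax(.data$n_evaluable, 1L)))
}

#' @export
tidy.mrecist_result <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.mrecist_result <- function(x, ...) {
  tibble::tibble(
    n = nrow(x),
    n_evaluable = sum(x$call != "unevaluable"),
    mcr_rate_pct = 100 * sum(x$call == "mCR") /
      max(sum(x$call != "unevaluable"), 1L),
    median_bar = stats::median(x$bar, na.rm = TRUE)
  )
}

#' Waterfall plot of an mRECIST result
#'
#' @param object A `mrecist_result` tibble.
#' @param ... Unused.
#' @return A ggplot: one bar per evaluable mouse, height = BAR, filled by
#'   response call, in waterfall order.
#' @export
autoplot.mrecist_result <- function(object, ...) {
  d <- cohort_waterfall(object)
  d <- d[!is.na(d$bar), , drop = FALSE]
  d$rank <- seq_len(nrow(d))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$bar,
                                  fill = .data$call)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(-40, -20, 30), linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::labs(x = "mouse (ranked)", y = "best average response (%)",
                  fill = "mRECIST") +
    ggplot2::theme_minimal()
}
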