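#' Cumulative (bilateral) tumor volume
#'
#' Sums one mouse's primary and secondary tumor volumes day by day on the
#' union of measured days. Measurement schedules can differ between sides,
#' so a side missing a given day contributes its last observed value
#' (carried forward); days before a side's first measurement contribute 0.
#' An entirely absent secondary curve leaves the primary unchanged.
#'
#' @param primary_curve,secondary_curve One-row curve tibbles for the same
#'   mouse (the secondary may have zero rows).
#' @return A one-row curve tibble with `tumor_site = "cumulative"`.
#' @export
cumulative_volume <- function(primary_curve, secondary_curve = NULL) {
  p <- as_curve(primary_curve)
  if (is.null(secondary_curve) ||
      (is.data.frame(secondary_curve) && nrow(secondary_curve) == 0)) {
    out <- tibble::as_tibble(primary_curve)
    out$tumor_site <- "cumulative"
    return(out)
  }
  s <- as_curve(secondary_curve)
  if (!identical(p$mouse_id, s$mouse_id)) {
    stop(sprintf("cumulative_volume: mismatched mice '%s' vs '%s'",
                 p$mouse_id, s$mouse_id), call. = FALSE)
  }
  days <- sort(union(p$measurements$day, s$measurements$day))
  vol <- locf_at(p$measurements, days) + locf_at(s$measurements, days)
  tibble::tibble(
    mouse_id = p$mouse_id, group = p$group, tumor_site = "cumulative",
    measurements = list(tibble::tibble(day = days, volume_mm3 = vol)),
    v_start = vol[days == 0][1] %||% NA_real_,
    followup_end = max(p$followup_end, s$followup_end),
    exit_reason = p$exit_reason
  )
}

# Last-observation-carried-forward lookup; 0 before the first measurement.
locf_at <- function(m, days) {
  idx <- findInterval(days, m$day)
  ifelse(idx == 0, 0, m$volume_mm3[pmax(idx, 1)])
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a

#' Time to a tumor-volume threshold
#'
#' The survival endpoint of the efficacy analyses: the first measured
#' post-treatment day on which the tumor volume reaches the threshold
#' (event), or censoring at the last observed day if the threshold is never
#' reached. No interpolation between measurement days is performed — the
#' event time is always a measured day.
#'
#' @param curve A one-row curve tibble.
#' @param threshold_mm3 Volume threshold (conventionally 500 or 1000 mm3).
#' @param scope Label recorded in the output: `"single"` for a single
#'   tumor, `"cumulative"` for a bilateral sum (see [cumulative_volume()]).
#' @return A one-row tibble: `mouse_id`, `group`, `time_days`, `event`,
#'   `threshold_mm3`, `scope`.
#' @export
time_to_threshold <- function(curve, threshold_mm3, scope = "single") {
  stopifnot(threshold_mm3 > 0)
  cv <- as_curve(curve)
  m <- cv$measurements[cv$measurements$day >= 0, , drop = FALSE]
  if (nrow(m) == 0) stop("time_to_threshold: empty curve", call. = FALSE)
  hit <- which(m$volume_mm3 >= threshold_mm3)
  tibble::tibble(
    mouse_id = cv$mouse_id, group = cv$group,
    time_days = if (length(hit) > 0) m$day[hit[1]] else max(m$day),
    event = length(hit) > 0,
    threshold_mm3 = threshold_mm3, scope = scope
  )
}

#' Survival records for a cohort
#'
#' Applies [time_to_threshold()] to every mouse. With
#' `scope = "cumulative"` the per-mouse bilateral sum is built first via
#' [cumulative_volume()]. Mice that exit for welfare or other reasons
#' before crossing are censored at their last observed day; only threshold
#' crossing counts as an event.
#'
#' @param curves A curve tibble.
#' @param threshold_mm3 Volume threshold (mm3).
#' @param scope `"single"` (primary tumor only) or `"cumulative"`.
#' @return A tibble of survival records, one row per mouse.
#' @export
survival_records <- function(curves, threshold_mm3 = 1000,
                             scope = c("single", "cumulative")) {
  scope <- match.arg(scope)
  purrr::map_dfr(unique(curves$mouse_id), function(id) {
    rows <- curves[curves$mouse_id == id, , drop = FALSE]
    target <- if (scope == "cumulative") {
      cumulative_volume(rows[rows$tumor_site == "primary", ],
                        rows[rows$tumor_site == "secondary", ])
    } else {
      rows[rows$tumor_site == "primary", ]
    }
    time_to_threshold(target, threshold_mm3, scope = scope)
  })
}

#' Kaplan-Meier fit of time-to-threshold records
#'
#' Product-limit estimate of the fraction of mice below the volume
#' threshold over time, overall or by group.
#'
#' @param records A survival-record tibble (see [survival_records()]).
#' @param by_group Stratify by the `group` column (default `TRUE` when
#'   present).
#' @return A `km_fit` object wrapping a [survival::survfit] fit.
#' @export
km_fit <- function(records, by_group = "group" %in% names(records)) {
  stopifnot(nrow(records) > 0)
  if (by_group) {
    fit <- survival::survfit(
      survival::Surv(time_days, event) ~ group,
      data = records)
  } else {
    fit <- survival::survfit(
      survival::Surv(time_days, event) ~ 1,
      data = records)
  }
  structure(list(fit = fit, records = records, by_group = by_group),
            class = "km_fit")
}

#' Median time-to-threshold
#'
#' The conventional Kaplan-Meier median: the smallest time at which the
#' survivor function drops to 0.5 or below; when the curve sits exactly at
#' 0.5 over an interval, the midpoint of that interval is reported (hence
#' half-day medians from even-sized, fully observed groups). `NA` means the
#' median was not reached.
#'
#' @param x A `km_fit` or a survival-record tibble.
#' @return A tibble `group`, `n`, `events`, `median_days`.
#' @export
km_median <- function(x) {
  if (!inherits(x, "km_fit")) x <- km_fit(x)
  tab <- summary(x$fit)$table
  if (is.null(dim(tab))) tab <- matrix(tab, nrow = 1,
                                       dimnames = list("all", names(tab)))
  tibble::tibble(
    group = sub("^group=", "", rownames(tab)),
    n = as.integer(tab[, "records"]),
    events = as.integer(tab[, "events"]),
    median_days = as.numeric(tab[, "median"])
  )
}

#' @export
tidy.km_fit <- function(x, ...) {
  f <- x$fit
  strata <- if (is.null(f$strata)) {
    rep("all", length(f$time))
  } else {
    sub("^group=", "", rep(names(f$strata), f$strata))
  }
  tibble::tibble(group = strata, time = f$time, n_risk = f$n.risk,
                 n_event = f$n.event, n_censor = f$n.censor,
                 estimate = f$surv)
}

#' @export
glance.km_fit <- function(x, ...) {
  med <- km_median(x)
  tibble::tibble(n = sum(med$n), events = sum(med$events),
                 n_groups = nrow(med))
}

#' @export
autoplot.km_fit <- function(object, ...) {
  d <- tidy(object)
  # prepend t = 0, S = 1 for each stratum so steps start at 1
  d0 <- dplyr::distinct(d, .data$group) |>
    dplyr::mutate(time = 0, estimate = 1)
  d <- dplyr::bind_rows(d0, d[, c("group", "time", "estimate")])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$estimate,
                                  color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "days after tumor irradiation",
                  y = "fraction below threshold", color = NULL) +
    ggplot2::theme_minimal()
}

#' Mantel-Cox logrank test
#'
#' Two-sided logrank comparison of two groups' time-to-threshold curves
#' (chi-square, 1 df). With no events in either group the test is
#' undefined; the function warns and reports statistic 0, p = 1.
#'
#' @param records_a,records_b Survival-record tibbles for the two groups.
#' @return A tibble `statistic`, `p_value`, `n_a`, `n_b`.
#' @export
logrank_test <- function(records_a, records_b) {
  stopifnot(nrow(records_a) > 0, nrow(records_b) > 0)
  if (!any(records_a$event) && !any(records_b$event)) {
    warning("logrank_test: no events in either group; p = 1")
    return(tibble::tibble(statistic = 0, p_value = 1,
                          n_a = nrow(records_a), n_b = nrow(records_b)))
  }
  d <- dplyr::bind_rows(
    dplyr::mutate(records_a, .arm = "a"),
    dplyr::mutate(records_b, .arm = "b")
  )
  sd <- survival::survdiff(survival::Surv(time_days, event) ~ .arm, data = d)
  tibble::tibble(statistic = sd$chisq,
                 p_value = stats::pchisq(sd$chisq, df = 1,
                                         lower.tail = FALSE),
                 n_a = nrow(records_a), n_b = nrow(records_b))
}

#' Pairwise logrank comparisons
#'
#' @param records A survival-record tibble with a `group` column.
#' @return A tibble with one row per unordered group pair.
#' @export
pairwise_logrank <- function(records) {
  groups <- unique(records$group)
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    res <- logrank_test(records[records$group == pr[1], , drop = FALSE],
                        records[records$group == pr[2], , drop = FALSE])
    dplyr::bind_cols(tibble::tibble(group_a = pr[1], group_b = pr[2]), res)
  })
}

#' Nadir response of the irradiated tumor
#'
#' Local-control criterion: a mouse responds when its post-treatment volume
#' nadir is at most 50% of the preceding maximum (a 50%-or-more decrease,
#' boundary inclusive). `v_max` is the maximum over measured days from day
#' 0 up to and including the nadir day — the decrease is measured against
#' the peak that precedes it. Monotonically growing tumors have nadir =
#' v_max at day 0 and never respond.
#'
#' @param curve A one-row curve tibble with at least two post-treatment
#'   measurements (fewer -> unevaluable, all-`NA` row).
#' @return A one-row tibble: `mouse_id`, `group`, `v_max`, `nadir`,
#'   `ratio`, `responder`.
#' @export
nadir_response <- function(curve) {
  cv <- as_curve(curve)
  m <- cv$measurements[cv$measurements$day >= 0, , drop = FALSE]
  if (nrow(m) < 2) {
    return(tibble::tibble(mouse_id = cv$mouse_id, group = cv$group,
                          v_max = NA_real_, nadir = NA_real_,
                          ratio = NA_real_, responder = NA))
  }
  i_nadir <- which.min(m$volume_mm3)
  nadir <- m$volume_mm3[i_nadir]
  v_max <- max(m$volume_mm3[seq_len(i_nadir)])
  ratio <- nadir / v_max
  tibble::tibble(mouse_id = cv$mouse_id, group = cv$group, v_max = v_max,
                 nadir = nadir, ratio = ratio, responder = ratio <= 0.5)
}

#' Nadir responders for a cohort
#'
#' @param curves A curve tibble (primary tumors are used).
#' @return A tibble with one [nadir_response()] row per mouse.
#' @export
cohort_nadir <- function(curves) {
  primary <- curves[curves$tumor_site == "primary", , drop = FALSE]
  purrr::map_dfr(seq_len(nrow(primary)),
                 function(i) nadir_response(primary[i, , drop = FALSE]))
}

#' Growth AUC with last-value carry-forward
#'
#' Trapezoidal integral of the tumor volume over \[0, `study_end`\] in
#' mm3 x days. Mice that exit before `study_end` would otherwise be
#' rewarded with a small AUC, so the curve is extended horizontally —
#' repeating the last measured value to the end of the study — which
#' partially corrects the comparison (Duan-style carry-forward). The
#' `extended` flag records whether the extension was applied.
#'
#' @param curve A one-row curve tibble.
#' @param study_end Integration end (days).
#' @return A one-row tibble: `mouse_id`, `group`, `auc`, `extended`.
#' @export
auc_lvcf <- function(curve, study_end) {
  cv <- as_curve(curve)
  m <- cv$measurements[cv$measurements$day >= 0 &
                         cv$measurements$day <= study_end, , drop = FALSE]
  if (nrow(m) == 0) stop("auc_lvcf: no post-treatment measurements",
                         call. = FALSE)
  auc <- trapezoid(m$day, m$volume_mm3)
  last_day <- max(m$day)
  extended <- last_day < study_end
  if (extended) {
    auc <- auc + m$volume_mm3[nrow(m)] * (study_end - last_day)
  }
  tibble::tibble(mouse_id = cv$mouse_id, group = cv$group, auc = auc,
                 extended = extended)
}

trapezoid <- function(x, y) {
  if (length(x) < 2) return(0)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Growth AUC for a cohort
#'
#' @param curves A curve tibble (primary tumors are used).
#' @param study_end Integration end (days); defaults to the curves'
#'   `followup_end`.
#' @return A tibble with one [auc_lvcf()] row per mouse.
#' @export
cohort_auc <- function(curves, study_end = max(curves$followup_end)) {
  primary <- curves[curves$tumor_site == "primary", , drop = FALSE]
  purrr::map_dfr(seq_len(nrow(primary)),
                 function(i) auc_lvcf(primary[i, , drop = FALSE], study_end))
}
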