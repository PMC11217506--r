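#' Cohort simulation parameters
#'
#' Bundles the parameters of the synthetic-cohort generator. The defaults
#' describe a subcutaneous B16F10-type melanoma study: tumors irradiated at a
#' mean volume of 80 mm3, exponential growth calibrated so an untreated tumor
#' reaches the 1000 mm3 endpoint in about two weeks, measurements every 2-3
#' days, and welfare truncation at a single-tumor burden of 1500 mm3 or a
#' bilateral cumulative burden of 2000 mm3.
#'
#' Responder classes:
#' \describe{
#'   \item{non_responder}{exponential growth \eqn{V_0 e^{g t}} throughout.}
#'   \item{transient_responder}{regression at `regression_rate` for
#'     `regrowth_delay_days`, then regrowth at `growth_rate`.}
#'   \item{durable_responder}{regression to the 1 mm3 detection floor and
#'     flat thereafter.}
#' }
#' Multiplicative log-normal measurement noise with coefficient of variation
#' `noise_cv` is applied to every measured volume; caliper readings cannot
#' report zero, so volumes are floored at 1 mm3.
#'
#' @param n_mice Number of mice.
#' @param class_mixture Named or positional probabilities over
#'   `c(non_responder, transient_responder, durable_responder)`; must sum
#'   to 1.
#' @param v0_mm3 Mean initial (day-0) tumor volume, mm3.
#' @param growth_rate Exponential growth rate g, per day.
#' @param regression_rate Post-treatment shrink rate, per day.
#' @param regrowth_delay_days Length of the regression phase for transient
#'   responders, days.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   log-normal measurement noise (0 = noise-free).
#' @param schedule_days Integer measurement days (day 0 must be included).
#' @param followup_end Last study day.
#' @param burden_limit_single,burden_limit_cumulative Welfare burden limits
#'   (mm3): a curve is truncated before the first scheduled day on which a
#'   limit would be exceeded, with `exit_reason = "welfare"`.
#' @param seed Integer seed; the whole cohort is reproducible from it, and
#'   per-mouse substreams are derived deterministically so partial
#'   re-simulation is stable.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_mice = 10,
                        class_mixture = c(non_responder = 1/3,
                                          transient_responder = 1/3,
                                          durable_responder = 1/3),
                        v0_mm3 = 80,
                        growth_rate = 0.18,
                        regression_rate = 0.25,
                        regrowth_delay_days = 7,
                        noise_cv = 0.15,
                        schedule_days = default_schedule(followup_end),
                        followup_end = 50,
                        burden_limit_single = 1500,
                        burden_limit_cumulative = 2000,
                        seed = 1L) {
  classes <- c("non_responder", "transient_responder", "durable_responder")
  mix <- as.numeric(class_mixture)
  if (length(mix) != 3 || any(mix < 0) || abs(sum(mix) - 1) > 1e-8) {
    stop("`class_mixture` must be 3 probabilities summing to 1", call. = FALSE)
  }
  names(mix) <- classes
  stopifnot(n_mice >= 0, v0_mm3 > 0, growth_rate > 0, regression_rate > 0,
            regrowth_delay_days >= 0, noise_cv >= 0,
            burden_limit_single > 0, burden_limit_cumulative > 0)
  schedule_days <- sort(unique(as.integer(schedule_days)))
  if (!0L %in% schedule_days) {
    stop("`schedule_days` must include day 0", call. = FALSE)
  }
  structure(list(
    n_mice = as.integer(n_mice), class_mixture = mix, v0_mm3 = v0_mm3,
    growth_rate = growth_rate, regression_rate = regression_rate,
    regrowth_delay_days = regrowth_delay_days, noise_cv = noise_cv,
    schedule_days = schedule_days, followup_end = as.integer(followup_end),
    burden_limit_single = burden_limit_single,
    burden_limit_cumulative = burden_limit_cumulative,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

# Every-2-3-day caliper schedule: 0, 3, 5, 8, 10, 13, ...
default_schedule <- function(followup_end) {
  steps <- cumsum(rep(c(3L, 2L), length.out = 2L * followup_end))
  c(0L, steps[steps <= followup_end])
}

detection_floor_mm3 <- 1

# Noise-free mean trajectory for one responder class.
mean_trajectory <- function(class, spec, v0, days) {
  g <- spec$growth_rate
  r <- spec$regression_rate
  d <- spec$regrowth_delay_days
  v <- switch(class,
    non_responder = v0 * exp(g * days),
    transient_responder = ifelse(days <= d,
                                 v0 * exp(-r * days),
                                 v0 * exp(-r * d) * exp(g * (days - d))),
    durable_responder = v0 * exp(-r * days),
    stop("unknown responder class: ", class, call. = FALSE)
  )
  pmax(v, detection_floor_mm3)
}

#' Simulate one growth curve
#'
#' Draws one mouse's measured volume series under the given responder class
#' and [cohort_spec()]. Measurement noise is multiplicative log-normal on the
#' volume; the series is truncated with `exit_reason = "welfare"` before the
#' first scheduled day whose measured volume would exceed
#' `burden_limit_single`, so no emitted volume ever exceeds the limit.
#'
#' @param class One of `"non_responder"`, `"transient_responder"`,
#'   `"durable_responder"`.
#' @param spec A [cohort_spec()].
#' @param mouse_id Identifier for the emitted curve.
#' @param group Group label.
#' @param seed Optional integer seed for this curve's private RNG stream
#'   (defaults to `spec$seed`); identical seeds give identical curves.
#' @return A one-row curve tibble in the [build_curves()] layout.
#' @export
simulate_growth_curve <- function(class, spec, mouse_id = "m1",
                                  group = "simulated", seed = spec$seed) {
  days <- spec$schedule_days[spec$schedule_days <= spec$followup_end]
  mu <- mean_trajectory(class, spec, spec$v0_mm3, days)
  v <- with_seed(seed, apply_noise(mu, spec$noise_cv, length(days)))
  over <- which(v > spec$burden_limit_single)
  exit_reason <- "study_end"
  if (length(over) > 0) {
    keep <- seq_len(over[1] - 1L)
    days <- days[keep]
    v <- v[keep]
    exit_reason <- "welfare"
  }
  tibble::tibble(
    mouse_id = mouse_id, group = group, tumor_site = "primary",
    measurements = list(tibble::tibble(day = days, volume_mm3 = v)),
    v_start = v[1],
    followup_end = spec$followup_end,
    exit_reason = exit_reason,
    class = class
  )
}

apply_noise <- function(mu, cv, n) {
  if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    mu <- mu * exp(stats::rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
  }
  pmax(mu, detection_floor_mm3)
}

#' Simulate a cohort of growth curves
#'
#' Draws `spec$n_mice` responder classes from `spec$class_mixture` and
#' simulates one primary-tumor curve per mouse. The true class labels are
#' returned in the `class` column so recovery of downstream response rates
#' can be tested. Fully reproducible from `spec$seed`; each mouse gets a
#' deterministic private RNG substream.
#'
#' @param spec A [cohort_spec()].
#' @param group Group label applied to every mouse.
#' @param secondary If `TRUE`, an untreated contralateral (secondary) tumor
#'   is simulated for every mouse alongside the primary, starting at
#'   `secondary_v0_frac` of the primary's initial volume and growing as a
#'   non-responder (the distant lesion is not irradiated). Both sides are
#'   then truncated before the first day on which the cumulative
#'   (primary + secondary) measured volume would exceed
#'   `burden_limit_cumulative`.
#' @param secondary_v0_frac Initial secondary/primary volume ratio.
#' @return A curve tibble (one row per mouse and tumor site) with a `class`
#'   column carrying the primary tumor's true responder class.
#' @export
simulate_cohort <- function(spec, group = "simulated", secondary = FALSE,
                            secondary_v0_frac = 0.5) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_mice
  if (n == 0) {
    return(tibble::tibble(mouse_id = character(), group = character(),
                          tumor_site = character(), measurements = list(),
                          v_start = numeric(), followup_end = integer(),
                          exit_reason = character(), class = character()))
  }
  classes <- names(spec$class_mixture)
  draws <- with_seed(spec$seed, {
    list(class = sample(classes, n, replace = TRUE, prob = spec$class_mixture),
         sub = sample.int(.Machine$integer.max - 2L, n),
         sub2 = sample.int(.Machine$integer.max - 2L, n))
  })
  out <- purrr::map_dfr(seq_len(n), function(i) {
    id <- sprintf("%s_%03d", group, i)
    prim <- simulate_growth_curve(draws$class[i], spec, mouse_id = id,
                                  group = group, seed = draws$sub[i])
    if (!secondary) return(prim)
    sec_spec <- spec
    sec_spec$v0_mm3 <- spec$v0_mm3 * secondary_v0_frac
    sec <- simulate_growth_curve("non_responder", sec_spec, mouse_id = id,
                                 group = group, seed = draws$sub2[i])
    sec$tumor_site <- "secondary"
    sec$class <- draws$class[i]
    truncate_cumulative(dplyr::bind_rows(prim, sec),
                        spec$burden_limit_cumulative)
  })
  out
}

# Truncate one mouse's primary+secondary pair so the carried-forward
# cumulative volume never exceeds the bilateral burden limit.
truncate_cumulative <- function(pair, limit) {
  cum <- cumulative_volume(pair[pair$tumor_site == "primary", ],
                           pair[pair$tumor_site == "secondary", ])
  cm <- cum$measurements[[1]]
  over <- which(cm$volume_mm3 > limit)
  if (length(over) == 0) return(pair)
  cut_day <- cm$day[over[1]]
  pair$measurements <- purrr::map(pair$measurements,
                                  ~ .x[.x$day < cut_day, , drop = FALSE])
  pair$exit_reason <- "welfare"
  pair
}

# Run expr under a temporary seed, restoring the global RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Flatten a curve tibble to a long measurement table
#'
#' Inverse of [build_curves()] for simulated cohorts: one row per mouse,
#' site and day, in the canonical CSV dialect.
#'
#' @param curves A curve tibble.
#' @return A measurement tibble.
#' @export
curves_to_measurements <- function(curves) {
  curves |>
    dplyr::select(dplyr::all_of(c("mouse_id", "group", "tumor_site",
                                  "measurements"))) |>
    tidyr::unnest("measurements") |>
    dplyr::mutate(length_mm = NA_real_, width_mm = NA_real_) |>
    dplyr::select(dplyr::all_of(measurement_cols))
}

#' Simulate an ex vivo lymph-node bioluminescence table
#'
#' Emulates the draining-lymph-node (DLN) metastasis readout: per mouse,
#' six average-radiance records (axillary, brachial, inguinal stations on
#' the draining and contralateral sides) plus a shared background-well
#' reading. A "positive" mouse carries, at one station, a draining signal
#' `signal_ratio` times its contralateral signal in expectation; negative
#' mice have symmetric signals (expected fold change 1).
#'
#' @param n_mice Number of mice.
#' @param positive_fraction Fraction of mice with nodal tumor spread.
#' @param signal_ratio Expected draining/contralateral corrected-signal
#'   ratio in positive mice (> 0).
#' @param background_mean Background-well average radiance (p/s/cm2/sr).
#' @param base_signal Mean contralateral corrected signal.
#' @param noise_cv Log-normal noise CV on every radiance (0 = noise-free).
#' @param seed Integer seed.
#' @return A tibble with columns `mouse_id`, `station`, `side`, `radiance`,
#'   `background`, plus the hidden truth column `metastatic`.
#' @export
simulate_bioluminescence <- function(n_mice, positive_fraction = 0.8,
                                     signal_ratio = 10,
                                     background_mean = 1000,
                                     base_signal = 2000,
                                     noise_cv = 0.2, seed = 1L) {
  stopifnot(positive_fraction >= 0, positive_fraction <= 1, signal_ratio > 0,
            background_mean >= 0, base_signal > 0, noise_cv >= 0)
  stations <- c("axillary", "brachial", "inguinal")
  with_seed(seed, {
    n_pos <- round(n_mice * positive_fraction)
    metastatic <- c(rep(TRUE, n_pos), rep(FALSE, n_mice - n_pos))
    purrr::map_dfr(seq_len(n_mice), function(i) {
      hot <- sample(stations, 1)
      grid <- tidyr::expand_grid(station = stations,
                                 side = c("draining", "contralateral"))
      mu <- ifelse(metastatic[i] & grid$side == "draining" &
                     grid$station == hot,
                   base_signal * signal_ratio, base_signal)
      noise <- if (noise_cv > 0) {
        sdlog <- sqrt(log(1 + noise_cv^2))
        exp(stats::rnorm(nrow(grid), -sdlog^2 / 2, sdlog))
      } else 1
      tibble::tibble(
        mouse_id = sprintf("m%03d", i),
        station = grid$station, side = grid$side,
        radiance = background_mean + mu * noise,
        background = background_mean,
        metastatic = metastatic[i]
      )
    })
  })
}
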