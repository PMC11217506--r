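test_that("cumulative volume sums sides with carry-forward on the day union", {
  p <- make_curve(c(0, 5), c(100, 600))
  s <- make_curve(c(0, 5), c(50, 500), tumor_site = "secondary")
  cum <- cumulative_volume(p, s)
  expect_equal(cum$measurements[[1]]$volume_mm3, c(150, 1100))

  # secondary absent entirely: identity
  alone <- cumulative_volume(p, NULL)
  expect_equal(alone$measurements[[1]], p$measurements[[1]])

  # mismatched schedules: last value carried forward
  p2 <- make_curve(c(0, 5), c(100, 600))
  s2 <- make_curve(c(0, 8), c(50, 700), tumor_site = "secondary")
  cum2 <- cumulative_volume(p2, s2)
  m <- cum2$measurements[[1]]
  expect_equal(m$day, c(0L, 5L, 8L))
  expect_equal(m$volume_mm3[m$day == 8], 600 + 700)
  # a side contributes 0 before its first measurement
  s3 <- make_curve(c(4, 8), c(50, 700), tumor_site = "secondary")
  cum3 <- cumulative_volume(p2, s3)
  expect_equal(cum3$measurements[[1]]$volume_mm3[1], 100)

  expect_error(cumulative_volume(p, make_curve(c(0, 5), c(1, 2),
                                               mouse_id = "other",
                                               tumor_site = "secondary")),
               "mismatched")
})

test_that("time to threshold picks the first measured crossing day", {
  cv <- make_curve(c(0, 7, 10), c(80, 400, 1200))
  rec <- time_to_threshold(cv, 1000)
  expect_true(rec$event)
  expect_equal(rec$time_days, 10)
  # never reached: censored at last observed day
  slow <- make_curve(c(0, 20, 50), c(80, 200, 400))
  rec2 <- time_to_threshold(slow, 1000)
  expect_false(rec2$event)
  expect_equal(rec2$time_days, 50)
  # degenerate: already above threshold at the first measured day
  big <- make_curve(0, 1200)
  rec3 <- time_to_threshold(big, 1000)
  expect_true(rec3$event)
  expect_equal(rec3$time_days, 0)
})

test_that("raising the threshold never shortens the time to event", {
  set.seed(404)
  for (i in 1:20) {
    days <- c(0L, sort(sample(1:40, 6)))
    vols <- 80 * exp(cumsum(c(0, rnorm(6, 0.2, 0.4))))
    cv <- make_curve(days, vols)
    lo <- time_to_threshold(cv, 500)
    hi <- time_to_threshold(cv, 1000)
    expect_gte(hi$time_days, lo$time_days)
    if (!lo$event) expect_false(hi$event)
  }
})

test_that("threshold crossing on noise-free exponential growth matches the closed form", {
  g <- 0.2; v0 <- 80; thr <- 1000
  spec <- cohort_spec(n_mice = 1, noise_cv = 0, growth_rate = g,
                      v0_mm3 = v0, schedule_days = 0:40, followup_end = 40,
                      burden_limit_single = 1e9, seed = 1)
  cv <- simulate_growth_curve("non_responder", spec)
  rec <- time_to_threshold(cv, thr)
  expect_equal(rec$time_days, ceiling(log(thr / v0) / g))
})

test_that("Kaplan-Meier estimate matches a hand product-limit computation", {
  rec <- tibble::tibble(mouse_id = as.character(1:3), group = "g",
                        time_days = c(10, 20, 30), event = TRUE,
                        threshold_mm3 = 1000, scope = "single")
  med <- km_median(rec)
  expect_equal(med$median_days, 20)
  fit <- km_fit(rec, by_group = FALSE)
  td <- tidy(fit)
  expect_equal(td$estimate, oracle_km(rec$time_days, rec$event)$surv)

  # without censoring KM is the empirical survivor function
  set.seed(7)
  t <- sample(5:60, 12, replace = TRUE)
  rec2 <- tibble::tibble(mouse_id = as.character(1:12), group = "g",
                         time_days = t, event = TRUE,
                         threshold_mm3 = 1000, scope = "single")
  td2 <- tidy(km_fit(rec2, by_group = FALSE))
  emp <- vapply(td2$time, function(x) mean(t > x), numeric(1))
  expect_equal(td2$estimate, emp)

  # all censored: survivor function stays at 1, median not reached
  cens <- dplyr::mutate(rec, event = FALSE)
  expect_true(is.na(km_median(cens)$median_days))

  # single mouse: step from 1 to 0 at its event time
  one <- rec[1, ]
  expect_equal(tidy(km_fit(one, by_group = FALSE))$estimate, 0)
})

test_that("an even group sitting exactly at S = 0.5 yields a half-day median", {
  rec <- tibble::tibble(mouse_id = as.character(1:6), group = "g",
                        time_days = c(30, 33, 36, 37, 40, 45), event = TRUE,
                        threshold_mm3 = 1000, scope = "single")
  expect_equal(km_median(rec)$median_days, 36.5)
})

test_that("logrank agrees with the direct Mantel-Cox formula", {
  mk <- function(t, e, g) tibble::tibble(
    mouse_id = paste0(g, seq_along(t)), group = g, time_days = t,
    event = e, threshold_mm3 = 1000, scope = "single")

  a <- mk(c(1, 2, 3), c(TRUE, TRUE, TRUE), "a")
  b <- mk(c(31, 32, 33), c(TRUE, TRUE, TRUE), "b")
  res <- logrank_test(a, b)
  oracle <- oracle_logrank(c(a$time_days, b$time_days),
                           c(a$event, b$event), rep(c(1, 0), each = 3))
  expect_equal(res$statistic, oracle$statistic, tolerance = 1e-8)
  expect_equal(res$p_value, oracle$p_value, tolerance = 1e-8)
  expect_lt(res$p_value, 0.05)

  # random instances, including censoring
  set.seed(505)
  for (i in 1:10) {
    t1 <- sample(1:30, 8, replace = TRUE)
    t2 <- sample(1:30, 6, replace = TRUE)
    e1 <- runif(8) < 0.8
    e2 <- runif(6) < 0.8
    if (!any(e1) && !any(e2)) e1[1] <- TRUE
    res <- logrank_test(mk(t1, e1, "a"), mk(t2, e2, "b"))
    oracle <- oracle_logrank(c(t1, t2), c(e1, e2),
                             rep(c(1, 0), c(8, 6)))
    expect_equal(res$statistic, oracle$statistic, tolerance = 1e-8)
    # symmetry under group swap
    swapped <- logrank_test(mk(t2, e2, "b"), mk(t1, e1, "a"))
    expect_equal(res$statistic, swapped$statistic, tolerance = 1e-10)
  }

  # identical event histories: no signal
  same <- logrank_test(mk(c(5, 9, 14), rep(TRUE, 3), "a"),
                       mk(c(5, 9, 14), rep(TRUE, 3), "b"))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1, tolerance = 1e-10)

  # no events anywhere: defined fallback with warning
  expect_warning(
    none <- logrank_test(mk(c(5, 9), c(FALSE, FALSE), "a"),
                         mk(c(7, 8), c(FALSE, FALSE), "b")),
    "no events")
  expect_equal(none$p_value, 1)
})

test_that("nadir response compares the minimum to the preceding peak", {
  cv <- make_curve(c(0, 3, 7, 10), c(100, 120, 50, 80))
  res <- nadir_response(cv)
  expect_equal(res$v_max, 120)
  expect_equal(res$nadir, 50)
  expect_equal(res$ratio, 50 / 120)
  expect_true(res$responder)

  # monotone growth: nadir = v_max at day 0, never a responder
  mono <- nadir_response(make_curve(c(0, 5, 10), c(80, 150, 400)))
  expect_false(mono$responder)
  expect_equal(mono$ratio, 1)

  # exactly 50%: inclusive boundary ("50% or more decrease")
  half <- nadir_response(make_curve(c(0, 6, 9), c(100, 100, 50)))
  expect_true(half$responder)

  # fewer than 2 post-treatment points: unevaluable
  single <- nadir_response(make_curve(0, 80))
  expect_true(is.na(single$responder))
})

test_that("growth AUC integrates trapezoidally and carries the last value forward", {
  flat <- make_curve(c(0, 5, 10), c(100, 100, 100))
  expect_equal(auc_lvcf(flat, 10)$auc, 1000)
  expect_false(auc_lvcf(flat, 10)$extended)

  ramp <- make_curve(c(0, 10), c(1e-9, 100))
  expect_equal(auc_lvcf(ramp, 10)$auc, 500, tolerance = 1e-6)

  # early exit: trapezoid to the last day, rectangle to study end
  early <- make_curve(c(0, 5), c(1e-9, 100))
  res <- auc_lvcf(early, 10)
  expect_equal(res$auc, 250 + 500, tolerance = 1e-6)
  expect_true(res$extended)

  # no early exit: equals the plain trapezoid rule on random curves
  set.seed(606)
  for (i in 1:10) {
    days <- c(0L, sort(sample(1:29, 5)), 30L)
    vols <- runif(7, 10, 900)
    got <- auc_lvcf(make_curve(days, vols), 30)$auc
    manual <- sum(diff(days) * (vols[-7] + vols[-1]) / 2)
    expect_equal(got, manual)
  }
})
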