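test_that("percent volume change and its running average match hand values", {
  ser <- volume_change_series(make_curve(c(0, 3, 7), c(80, 160, 4)))
  expect_equal(ser$delta_v, c(0, 100, -95))
  # running average is the count-based mean over measured days
  ser3 <- volume_change_series(make_curve(c(0, 3, 7), c(100, 50, 25)))
  expect_equal(ser3$delta_v_bar, c(0, mean(c(0, -50)), mean(c(0, -50, -75))))
  # constant curve: change identically zero
  flat <- volume_change_series(make_curve(c(0, 4, 9), c(80, 80, 80)))
  expect_equal(flat$delta_v_bar, c(0, 0, 0))
})

test_that("day-index denominator variant reduces to the printed formula", {
  cv <- make_curve(c(0, 2, 4), c(100, 150, 50))
  ser <- volume_change_series(cv, denominator = "day")
  # sum of changes through day d divided by d
  expect_equal(ser$delta_v_bar, c(0, 50 / 2, (0 + 50 - 50) / 4))
})

test_that("BR and BAR take minima over days at or after min_day only", {
  ser <- tibble::tibble(day = c(0L, 3L, 7L, 10L),
                        delta_v = c(0, -99, -80, -70),
                        delta_v_bar = c(0, -49.5, -59.7, -62.2))
  expect_equal(best_response(ser), -80)   # the day-3 nadir is ineligible
  expect_equal(best_average_response(ser), -62.2)
  early <- tibble::tibble(day = c(0L, 5L), delta_v = c(0, -90),
                          delta_v_bar = c(0, -45))
  expect_true(is.na(best_response(early)))
  expect_true(is.na(best_average_response(early)))
  expect_equal(best_response(ser, min_day = 10), -70)
})

test_that("response calls use strict thresholds in precedence order", {
  expect_equal(classify_response(-100, -80), "mCR")
  expect_equal(classify_response(-60, -25), "mPR")
  expect_equal(classify_response(0, 10), "mSD")
  expect_equal(classify_response(40, 35), "mPD")
  # exact boundary: strict inequality fails mCR, lands in mPR
  expect_equal(classify_response(-95, -40), "mPR")
  expect_equal(classify_response(-50, -20), "mSD")
  expect_equal(classify_response(35, 29), "mPD")
  expect_equal(classify_response(NA, -50), "unevaluable")
})

test_that("scoring is invariant to volume rescaling and lost mice stay visible", {
  set.seed(101)
  for (i in 1:25) {
    days <- sort(sample(0:30, 6))
    days[1] <- 0L
    vols <- exp(runif(6, log(5), log(1200)))
    a <- mrecist_score(make_curve(days, vols))
    b <- mrecist_score(make_curve(days, vols * runif(1, 0.1, 10)))
    expect_equal(a$br, b$br)
    expect_equal(a$bar, b$bar)
    expect_equal(a$call, b$call)
  }
  short <- mrecist_score(make_curve(c(0, 5), c(80, 40)))
  expect_equal(as.character(short$call), "unevaluable")
})

test_that("pointwise-lower volume series never worsen the call", {
  rank_call <- function(x) match(x, c("mCR", "mPR", "mSD", "mPD"))
  set.seed(202)
  for (i in 1:25) {
    days <- c(0L, sort(sample(1:30, 5)))
    vols <- exp(runif(6, log(10), log(1000)))
    vols[1] <- 80
    shrink <- c(1, runif(5, 0.3, 1))  # lower everywhere after day 0
    hi <- mrecist_score(make_curve(days, vols))
    lo <- mrecist_score(make_curve(days, vols * shrink))
    expect_lte(rank_call(as.character(lo$call)),
               rank_call(as.character(hi$call)))
    # BR bounds every eligible daily change from below
    ser <- volume_change_series(make_curve(days, vols))
    expect_true(all(hi$br <= ser$delta_v[ser$day >= 7]))
    expect_true(all(hi$bar <= ser$delta_v_bar[ser$day >= 7]))
  }
})

test_that("an mCR call implies a deep nadir after the evaluation window opens", {
  set.seed(303)
  for (i in 1:20) {
    days <- c(0L, sort(sample(1:40, 7)))
    vols <- 80 * exp(cumsum(c(0, rnorm(7, -0.4, 0.6))))
    sc <- mrecist_score(make_curve(days, pmax(vols, 0.5)))
    if (!is.na(sc$br) && sc$br < -95) {
      post <- pmax(vols, 0.5)[days >= 7]
      expect_lt(min(post), 0.05 * 80)
    }
  }
})

test_that("cohort waterfall matches an independent re-scoring of every curve", {
  spec <- cohort_spec(n_mice = 40, noise_cv = 0.2, seed = 55)
  coh <- simulate_cohort(spec)
  wf <- cohort_waterfall(coh)
  expect_equal(wf$bar, sort(wf$bar, decreasing = TRUE))
  for (i in seq_len(nrow(coh))) {
    m <- coh$measurements[[i]]
    oracle <- oracle_mrecist(m$day, m$volume_mm3)
    row <- wf[wf$mouse_id == coh$mouse_id[i], ]
    expect_equal(row$br, oracle$br)
    expect_equal(row$bar, oracle$bar)
    expect_equal(as.character(row$call), oracle$call)
  }
  expect_equal(nrow(cohort_waterfall(coh[0, ])), 0)
})

test_that("group response rates sum correctly and use evaluable denominators", {
  curves <- dplyr::bind_rows(
    make_curve(c(0, 7), c(80, 2), mouse_id = "m1"),     # mCR
    make_curve(c(0, 7), c(80, 300), mouse_id = "m2"),   # mPD
    make_curve(c(0, 5), c(80, 100), mouse_id = "m3")    # unevaluable
  )
  rates <- mrecist_rates(mrecist_score(curves))
  mcr <- rates[rates$call == "mCR", ]
  expect_equal(mcr$n_evaluable, 2L)
  expect_equal(mcr$rate_pct, 50)
  expect_equal(sum(rates$n), 3L)
})
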