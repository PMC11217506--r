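# Shared fixtures and independent oracles used across the suite.
# The oracles are deliberately naive, straight-line computations that never
# call the package's own code paths.

make_curve <- function(days, volumes, mouse_id = "m1", group = "g",
                       tumor_site = "primary",
                       followup_end = max(days),
                       exit_reason = "study_end") {
  tibble::tibble(
    mouse_id = mouse_id, group = group, tumor_site = tumor_site,
    measurements = list(tibble::tibble(day = as.integer(days),
                                       volume_mm3 = volumes)),
    v_start = if (0 %in% days) volumes[days == 0][1] else NA_real_,
    followup_end = as.integer(followup_end), exit_reason = exit_reason
  )
}

# Straight-line mRECIST re-scoring: percent change, count-based running
# mean, minima over day >= min_day, ordered strict thresholds.
oracle_mrecist <- function(days, volumes, min_day = 7) {
  keep <- days >= 0
  days <- days[keep]; volumes <- volumes[keep]
  v0 <- volumes[days == 0][1]
  dv <- numeric(length(days))
  dvbar <- numeric(length(days))
  for (i in seq_along(days)) {
    dv[i] <- 100 * (volumes[i] - v0) / v0
    dvbar[i] <- mean(dv[1:i])
  }
  sel <- days >= min_day
  if (!any(sel)) return(list(br = NA_real_, bar = NA_real_,
                             call = "unevaluable"))
  br <- min(dv[sel]); bar <- min(dvbar[sel])
  call <- if (br < -95 && bar < -40) "mCR"
  else if (br < -50 && bar < -20) "mPR"
  else if (br < 35 && bar < 30) "mSD"
  else "mPD"
  list(br = br, bar = bar, call = call)
}

# Direct Mantel-Cox formula: observed-minus-expected events in group 1
# over the shared risk sets, squared over the hypergeometric variance.
oracle_logrank <- function(time, event, arm) {
  ts <- sort(unique(time[event]))
  o_minus_e <- 0
  varsum <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & arm == 1)
    d <- sum(event & time == t)
    d1 <- sum(event & time == t & arm == 1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) {
      varsum <- varsum + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
  }
  chisq <- o_minus_e^2 / varsum
  list(statistic = chisq, p_value = pchisq(chisq, 1, lower.tail = FALSE))
}

# Exhaustive two-sided Fisher p: enumerate every table with the observed
# margins, sum the probabilities not exceeding the observed table's.
oracle_fisher <- function(tb) {
  r1 <- sum(tb[1, ]); c1 <- sum(tb[, 1]); n <- sum(tb)
  xs <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(xs, c1, n - c1, r1)
  p_obs <- dhyper(tb[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Hand product-limit estimator (no ties in censoring assumptions needed).
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event]))
  s <- 1
  out <- data.frame(time = ts, surv = NA_real_)
  for (i in seq_along(ts)) {
    n_risk <- sum(time >= ts[i])
    d <- sum(event & time == ts[i])
    s <- s * (1 - d / n_risk)
    out$surv[i] <- s
  }
  out
}
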