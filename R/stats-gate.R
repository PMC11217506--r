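#' Grubbs outlier screen
#'
#' Single-pass two-sided Grubbs test: the most extreme value is removed
#' when its standardized deviation \eqn{G = \max|x_i - \bar x| / s}
#' exceeds the critical value
#' \deqn{\frac{n-1}{\sqrt n}\sqrt{\frac{t^2}{n-2+t^2}},\quad
#'       t = t_{\alpha/(2n),\,n-2},}
#' at most one value per call (iterated removal inflates the false-exclusion
#' rate). Samples with fewer than 3 values or zero variance are returned
#' unchanged with a warning.
#'
#' @param values Numeric vector.
#' @param alpha Significance level (default 0.05).
#' @return A list: `kept` (values retained), `removed` (length 0 or 1),
#'   `g` (the observed statistic, `NA` when not testable), `critical`.
#' @export
grubbs_filter <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3 || stats::sd(values) == 0) {
    warning("grubbs_filter: need n >= 3 and non-zero variance; no-op")
    return(list(kept = values, removed = numeric(0), g = NA_real_,
                critical = NA_real_))
  }
  dev <- abs(values - mean(values))
  g <- max(dev) / stats::sd(values)
  tcrit <- stats::qt(1 - alpha / (2 * n), df = n - 2)
  critical <- (n - 1) / sqrt(n) * sqrt(tcrit^2 / (n - 2 + tcrit^2))
  if (g > critical) {
    drop <- which.max(dev)
    list(kept = values[-drop], removed = values[drop], g = g,
         critical = critical)
  } else {
    list(kept = values, removed = numeric(0), g = g, critical = critical)
  }
}

#' Shapiro-Wilk normality gate
#'
#' Decides between the parametric and nonparametric comparison branch:
#' parametric only when every group passes the Shapiro-Wilk test
#' (p >= alpha). A group too small to test (n < 3) forces the
#' nonparametric branch with a warning — normality cannot be asserted.
#'
#' @param groups A list of numeric vectors (one per treatment group).
#' @param alpha Gate level (default 0.05).
#' @return `"parametric"` or `"nonparametric"`.
#' @export
normality_gate <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 1)
  sizes <- vapply(groups, function(g) sum(!is.na(g)), integer(1))
  if (any(sizes < 3)) {
    warning("normality_gate: group with n < 3; using nonparametric branch")
    return("nonparametric")
  }
  p <- vapply(groups, function(g) stats::shapiro.test(g)$p.value, numeric(1))
  if (all(p >= alpha)) "parametric" else "nonparametric"
}

# Holm-Sidak step-down adjustment: order raw p ascending, adjust the i-th
# as 1 - (1 - p)^(m - i + 1), then enforce monotonicity.
holm_sidak <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Pairwise t comparisons with the pooled ANOVA error variance,
# Holm-Sidak corrected.
pairwise_pooled_t <- function(values, groups) {
  lv <- unique(groups)
  fit <- stats::aov(values ~ factor(groups))
  mse <- sum(stats::residuals(fit)^2) / fit$df.residual
  df <- fit$df.residual
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  res <- purrr::map_dfr(pairs, function(pr) {
    xa <- values[groups == pr[1]]
    xb <- values[groups == pr[2]]
    se <- sqrt(mse * (1 / length(xa) + 1 / length(xb)))
    tstat <- (mean(xa) - mean(xb)) / se
    tibble::tibble(group_a = as.character(pr[1]),
                   group_b = as.character(pr[2]),
                   statistic = tstat,
                   p_raw = 2 * stats::pt(-abs(tstat), df))
  })
  res$p_adj <- holm_sidak(res$p_raw)
  res
}

# Dunn's post-hoc z comparisons on ranks with tie correction, adjusted
# over all pairwise comparisons (Bonferroni-style multiplicity, the usual
# companion to Kruskal-Wallis).
dunn_pairwise <- function(values, groups) {
  lv <- unique(groups)
  r <- rank(values)
  n <- length(values)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  res <- purrr::map_dfr(pairs, function(pr) {
    ra <- r[groups == pr[1]]
    rb <- r[groups == pr[2]]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) *
                 (1 / length(ra) + 1 / length(rb)))
    z <- (mean(ra) - mean(rb)) / se
    tibble::tibble(group_a = as.character(pr[1]),
                   group_b = as.character(pr[2]),
                   statistic = z,
                   p_raw = 2 * stats::pnorm(-abs(z)))
  })
  res$p_adj <- pmin(res$p_raw * length(pairs), 1)
  res
}

#' Normality-gated group comparison
#'
#' The study's statistical dispatch: values are screened per group with the
#' Grubbs test (optional), gated through Shapiro-Wilk, and compared with
#' \itemize{
#'   \item two groups, parametric: two-sided unpaired t test;
#'   \item more than two, parametric: one-way ANOVA with Holm-Sidak
#'     pairwise comparisons (pooled error variance);
#'   \item two groups, nonparametric: two-sided Mann-Whitney (exact when
#'     the combined n is at most 20 and untied, normal approximation with
#'     tie correction otherwise);
#'   \item more than two, nonparametric: Kruskal-Wallis with Dunn's
#'     multiple comparisons.
#' }
#' A second factor (`block`) switches to two-way ANOVA with Holm-Sidak
#' comparisons of the primary factor within each block level (no
#' nonparametric two-way branch is offered; the gate is still reported).
#'
#' @param data A data frame.
#' @param value,group Column names (strings) of the measured value and the
#'   treatment group.
#' @param block Optional second-factor column name for a factorial design.
#' @param alpha Gate and test level (default 0.05).
#' @param grubbs Apply [grubbs_filter()] per group first (default FALSE).
#' @return A `group_comparison` object: list with `test_name`, `branch`,
#'   `statistic`, `p_value` (omnibus, where defined), `pairwise` (tibble
#'   with corrected p per pair, `NULL` for two groups), `alpha`, `removed`
#'   (Grubbs-excluded values).
#' @export
compare_groups <- function(data, value, group, block = NULL, alpha = 0.05,
                           grubbs = FALSE) {
  v <- data[[value]]
  g <- as.character(data[[group]])
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- g[keep]
  lv <- unique(g)
  if (length(lv) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(g) == 0)) stop("empty group", call. = FALSE)

  removed <- numeric(0)
  if (grubbs && !is.null(block)) {
    stop("Grubbs screening is per-group and not defined for factorial designs",
         call. = FALSE)
  }
  if (grubbs) {
    filtered <- purrr::map(lv, function(l) {
      suppressWarnings(grubbs_filter(v[g == l], alpha))
    })
    removed <- unlist(purrr::map(filtered, "removed"))
    v <- unlist(purrr::map(filtered, "kept"))
    g <- rep(lv, vapply(filtered, function(f) length(f$kept), integer(1)))
  }

  blocked <- !is.null(block)
  branch <- suppressWarnings(
    normality_gate(split(v, g), alpha = alpha))

  if (blocked) {
    b <- as.character(data[[block]])[keep]
    fit <- stats::aov(v ~ factor(g) * factor(b))
    an <- summary(fit)[[1]]
    pw <- purrr::map_dfr(unique(b), function(bl) {
      sub <- pairwise_pooled_t(v[b == bl], g[b == bl])
      sub$block <- bl
      sub
    })
    pw$p_adj <- holm_sidak(pw$p_raw)
    res <- list(test_name = "two_way_anova_holm_sidak", branch = branch,
                statistic = an["factor(g)", "F value"],
                p_value = an["factor(g)", "Pr(>F)"],
                pairwise = pw, alpha = alpha, removed = removed)
  } else if (branch == "parametric" && length(lv) == 2) {
    tt <- stats::t.test(v[g == lv[1]], v[g == lv[2]], var.equal = TRUE)
    res <- list(test_name = "t_unpaired", branch = branch,
                statistic = unname(tt$statistic), p_value = tt$p.value,
                pairwise = NULL, alpha = alpha, removed = removed)
  } else if (branch == "parametric") {
    fit <- stats::aov(v ~ factor(g))
    an <- summary(fit)[[1]]
    res <- list(test_name = "anova_holm_sidak", branch = branch,
                statistic = an[1, "F value"], p_value = an[1, "Pr(>F)"],
                pairwise = pairwise_pooled_t(v, g), alpha = alpha,
                removed = removed)
  } else if (length(lv) == 2) {
    exact <- length(v) <= 20 && !any(duplicated(v))
    mw <- suppressWarnings(
      stats::wilcox.test(v[g == lv[1]], v[g == lv[2]], exact = exact,
                         correct = !exact))
    res <- list(test_name = "mann_whitney", branch = "nonparametric",
                statistic = unname(mw$statistic), p_value = mw$p.value,
                pairwise = NULL, alpha = alpha, removed = removed)
  } else {
    kw <- stats::kruskal.test(v, factor(g))
    res <- list(test_name = "kruskal_dunn", branch = "nonparametric",
                statistic = unname(kw$statistic), p_value = kw$p.value,
                pairwise = dunn_pairwise(v, g), alpha = alpha,
                removed = removed)
  }
  structure(res, class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s (%s branch)\n", x$test_name, x$branch))
  cat(sprintf("  statistic = %.4g, p = %.4g (alpha = %g)\n",
              x$statistic, x$p_value, x$alpha))
  if (!is.null(x$pairwise)) {
    cat("  pairwise (corrected):\n")
    print(as.data.frame(x$pairwise), row.names = FALSE)
  }
  invisible(x)
}

#' @export
tidy.group_comparison <- function(x, ...) {
  if (!is.null(x$pairwise)) {
    dplyr::mutate(x$pairwise, test_name = x$test_name, branch = x$branch)
  } else {
    tibble::tibble(group_a = NA_character_, group_b = NA_character_,
                   statistic = x$statistic, p_raw = x$p_value,
                   p_adj = x$p_value, test_name = x$test_name,
                   branch = x$branch)
  }
}

#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(test_name = x$test_name, branch = x$branch,
                 statistic = x$statistic, p_value = x$p_value,
                 alpha = x$alpha, n_removed = length(x$removed))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric test: the two-sided p-value sums the probabilities
#' of all tables with the observed margins that are no more probable than
#' the observed one.
#'
#' @param table_2x2 A 2x2 matrix of non-negative integer counts.
#' @return The two-sided p-value.
#' @export
fisher_exact <- function(table_2x2) {
  tb <- as.matrix(table_2x2)
  if (!all(dim(tb) == c(2, 2)) || any(tb < 0) || any(tb != round(tb))) {
    stop("`table_2x2` must be a 2x2 matrix of non-negative integers",
         call. = FALSE)
  }
  stats::fisher.test(tb)$p.value
}
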