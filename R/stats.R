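#' One-sample Kolmogorov-Smirnov normality check
#'
#' Tests the sample against a normal distribution whose mean and sd are
#' estimated from the sample itself, using the asymptotic KS distribution
#' for the p-value.  Because the reference parameters are estimated, the
#' nominal p-value is conservative (the Lilliefors caveat); the result
#' carries an explicit flag rather than silently substituting a different
#' test.
#'
#' @param x numeric sample, n >= 3.
#' @return list with `statistic` (D), `p_value`, `n`, and
#'   `estimated_params = TRUE` with a `caveat` string.
#' @export
ks_normality <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (sd(x) == 0) stop("zero-variance sample: KS test undefined",
                       call. = FALSE)
  kt <- suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x), exact = FALSE))
  list(statistic = unname(kt$statistic), p_value = kt$p.value, n = length(x),
       estimated_params = TRUE,
       caveat = paste("reference mean/sd estimated from the sample;",
                      "asymptotic p-value is conservative (Lilliefors caveat)"))
}

#' Bonferroni correction
#'
#' `p_adj = min(1, m * p)` with `m = length(p)`.
#'
#' @param p vector of p-values in \[0, 1\].
#' @return adjusted p-values.
#' @export
bonferroni <- function(p) {
  stopifnot(is.numeric(p), all(p >= 0 & p <= 1))
  p.adjust(p, method = "bonferroni")
}

#' Tukey-Kramer HSD all-pairs comparisons
#'
#' Pairwise mean comparisons with family-wise error control via the
#' studentized range distribution.  The pooled within-group variance is used
#' with the Kramer modification for unequal group sizes:
#' `SE_ij = sqrt(s2/2 * (1/n_i + 1/n_j))`, `q_ij = |m_i - m_j| / SE_ij`, and
#' the adjusted p-value is the upper tail of the studentized range with
#' `k` groups and `N - k` degrees of freedom.  Family-wise confidence
#' intervals use the corresponding studentized range quantile.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 2).
#' @param level family-wise confidence level.
#' @return data frame of class `hsd_result`: one row per pair with
#'   `diff` (mean difference), `se`, `q`, `p_adj`, `lwr`, `upr`.
#' @export
tukey_hsd <- function(groups, level = 0.95) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  n <- vapply(groups, length, integer(1))
  if (any(n < 2L)) stop("every group needs at least 2 observations",
                        call. = FALSE)
  k <- length(groups)
  N <- sum(n)
  m <- vapply(groups, mean, numeric(1))
  s2 <- sum(vapply(groups, function(g) (length(g) - 1) * var(g), numeric(1))) /
    (N - k)
  if (!is.finite(s2) || s2 <= 0) {
    stop("zero pooled within-group variance: HSD undefined", call. = FALSE)
  }
  df <- N - k
  qcrit <- qtukey(level, nmeans = k, df = df)
  pairs <- utils::combn(k, 2)
  out <- data.frame(
    comparison = character(ncol(pairs)), diff = NA_real_, se = NA_real_,
    q = NA_real_, p_adj = NA_real_, lwr = NA_real_, upr = NA_real_,
    stringsAsFactors = FALSE
  )
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt(s2 / 2 * (1 / n[a] + 1 / n[b]))
    d <- m[a] - m[b]
    q <- abs(d) / se
    out$comparison[j] <- paste(names(groups)[a], "-", names(groups)[b])
    out$diff[j] <- d
    out$se[j] <- se
    out$q[j] <- q
    out$p_adj[j] <- ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
    out$lwr[j] <- d - qcrit * se
    out$upr[j] <- d + qcrit * se
  }
  attr(out, "df") <- df
  attr(out, "pooled_variance") <- s2
  attr(out, "level") <- level
  class(out) <- c("hsd_result", "data.frame")
  out
}

#' Significance stars for adjusted p-values
#'
#' Conventional mapping: `***` p < 0.001, `**` p < 0.01, `*` p < 0.05
#' (the significance criterion used throughout the package), `ns` otherwise.
#'
#' @param p numeric p-values.
#' @return character vector of symbols.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' OLS agreement model between manual and software counts
#'
#' Fits `manual ~ software` by ordinary least squares and reports the slope
#' and intercept with their 95% confidence intervals (t distribution,
#' df = n - 2), t statistics and p-values, R-squared and adjusted R-squared,
#' plus the standardized beta obtained by refitting on z-scored variables.
#' Perfect agreement corresponds to slope 1, intercept 0, R-squared 1.
#'
#' @param manual,software paired numeric count vectors, n >= 3.
#' @param level confidence level for the intervals.
#' @return list of class `agreement_result`.
#' @export
agreement_model <- function(manual, software, level = 0.95) {
  stopifnot(length(manual) == length(software))
  n <- length(manual)
  if (n < 3L) stop("need at least 3 paired counts", call. = FALSE)
  if (var(software) == 0) stop("zero variance in software counts",
                               call. = FALSE)
  fit <- lm(manual ~ software)
  sm <- summary(fit)
  ci <- confint(fit, level = level)
  zfit <- lm(scale(manual) ~ scale(software))
  zci <- confint(zfit, level = level)
  out <- list(
    slope = unname(coef(fit)[2]),
    slope_ci = unname(ci[2, ]),
    intercept = unname(coef(fit)[1]),
    intercept_ci = unname(ci[1, ]),
    t = unname(sm$coefficients[, "t value"]),
    p = unname(sm$coefficients[, "Pr(>|t|)"]),
    df = n - 2L,
    r_squared = sm$r.squared,
    adj_r_squared = sm$adj.r.squared,
    std_beta = unname(coef(zfit)[2]),
    std_beta_ci = unname(zci[2, ]),
    n = n
  )
  class(out) <- "agreement_result"
  out
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<agreement_result> n = %d, R^2 = %.4f (adj %.4f)\n",
              x$n, x$r_squared, x$adj_r_squared))
  cat(sprintf("  slope     %.4f  [%.4f, %.4f]  t(%d) = %.2f, p = %.3g\n",
              x$slope, x$slope_ci[1], x$slope_ci[2], x$df, x$t[2], x$p[2]))
  cat(sprintf("  intercept %.4f  [%.4f, %.4f]  t(%d) = %.2f, p = %.3g\n",
              x$intercept, x$intercept_ci[1], x$intercept_ci[2], x$df,
              x$t[1], x$p[1]))
  cat(sprintf("  std beta  %.4f  [%.4f, %.4f]\n",
              x$std_beta, x$std_beta_ci[1], x$std_beta_ci[2]))
  invisible(x)
}

#' Relative difference between two counts
#'
#' `100 * |b - a| / a`, with a rounded-to-integer presentation value; the
#' convention used to compare a manual reference count `a` with a software
#' count `b`.
#'
#' @param a reference count (> 0).
#' @param b comparison count.
#' @return list with `percent` and `rounded_percent`.
#' @export
relative_difference <- function(a, b) {
  if (!is.numeric(a) || a <= 0) stop("reference count a must be > 0",
                                     call. = FALSE)
  pct <- 100 * abs(b - a) / a
  list(percent = pct, rounded_percent = round(pct))
}
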