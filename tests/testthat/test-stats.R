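test_that("KS normality check matches a brute-force ECDF scan", {
  # a sample on the normal quantile grid is as normal as it gets
  x <- qnorm((1:50) / 51)
  r <- ks_normality(x)
  expect_lt(r$statistic, 0.05)
  expect_true(r$estimated_params)

  # a uniform sample is flagged as non-normal
  u <- wellcounter:::with_seed(42L, runif(500))
  ru <- ks_normality(u)
  expect_lt(ru$p_value, 0.05)

  # D equals the brute-force max over sample points of |F_hat - F|
  set.seed(9)
  y <- rnorm(40, 2, 3)
  ry <- ks_normality(y)
  Fy <- pnorm(sort(y), mean(y), sd(y))
  n <- length(y)
  d_brute <- max(pmax((1:n) / n - Fy, Fy - (0:(n - 1)) / n))
  expect_equal(ry$statistic, d_brute, tolerance = 1e-12)

  expect_error(ks_normality(rep(1, 10)), "zero-variance")
  expect_error(ks_normality(c(1, 2)), "at least 3")
})

test_that("bonferroni clamps, preserves order and is idempotent", {
  expect_equal(bonferroni(c(0.01, 0.02)), c(0.02, 0.04))
  expect_equal(bonferroni(0.2), 0.2)
  expect_equal(bonferroni(c(0.6, 0.9)), c(1, 1))
  set.seed(5)
  p <- runif(20)
  adj <- bonferroni(p)
  expect_true(all(order(adj) == order(pmin(1, 20 * p))))
  # idempotent after clamping at 1: re-adjusting all-1 vectors changes nothing
  expect_equal(bonferroni(bonferroni(c(0.6, 0.9))), c(1, 1))
})

test_that("two-group Tukey-Kramer equals the pooled t-test via q = |t|*sqrt(2)", {
  set.seed(1)
  g1 <- rnorm(6); g2 <- rnorm(8, 0.5)
  h <- tukey_hsd(list(a = g1, b = g2))
  tt <- t.test(g1, g2, var.equal = TRUE)
  expect_equal(h$p_adj, tt$p.value, tolerance = 1e-6)
  expect_equal(h$q, abs(tt$statistic[[1]]) * sqrt(2), tolerance = 1e-10)
})

test_that("Tukey-Kramer agrees with stats::TukeyHSD on unbalanced groups", {
  set.seed(2)
  vals <- c(rnorm(5), rnorm(7, 1), rnorm(6, 3))
  grp <- factor(rep(c("g1", "g2", "g3"), c(5, 7, 6)))
  h <- tukey_hsd(split(vals, grp))
  ref <- TukeyHSD(aov(vals ~ grp))$grp
  # same pairs, opposite sign convention (ref is second - first)
  expect_equal(h$p_adj, unname(ref[, "p adj"]), tolerance = 1e-6)
  expect_equal(h$diff, -unname(ref[, "diff"]), tolerance = 1e-10)
  expect_equal(h$lwr, -unname(ref[, "upr"]), tolerance = 1e-8)
  expect_equal(h$upr, -unname(ref[, "lwr"]), tolerance = 1e-8)
})

test_that("Tukey-Kramer null, separated and degenerate configurations", {
  # identical groups: all differences 0, all p = 1
  g <- c(1, 2, 3, 4)
  h0 <- tukey_hsd(list(a = g, b = g, c = g))
  expect_true(all(h0$diff == 0))
  expect_true(all(h0$p_adj > 1 - 1e-9))

  # one clearly separated group
  set.seed(3)
  h1 <- tukey_hsd(list(a = rnorm(5, 0, 0.1), b = rnorm(5, 0, 0.1),
                       c = rnorm(5, 10, 0.1)))
  expect_lt(h1$p_adj[h1$comparison == "a - c"], 0.001)
  expect_lt(h1$p_adj[h1$comparison == "b - c"], 0.001)
  expect_gt(h1$p_adj[h1$comparison == "a - b"], 0.05)

  # adjusted p-values dominate the unadjusted pairwise t-tests
  set.seed(4)
  gs <- list(a = rnorm(6), b = rnorm(5, 0.8), c = rnorm(7, 1.5))
  h <- tukey_hsd(gs)
  raw <- c(t.test(gs$a, gs$b, var.equal = TRUE)$p.value,
           t.test(gs$a, gs$c, var.equal = TRUE)$p.value,
           t.test(gs$b, gs$c, var.equal = TRUE)$p.value)
  expect_true(all(h$p_adj >= raw - 1e-10))

  expect_error(tukey_hsd(list(a = c(1, 1), b = c(1, 1))), "zero")
  expect_error(tukey_hsd(list(a = 1:3)), "length")
})

test_that("agreement model reproduces the OLS closed forms", {
  # identity data
  x <- c(10, 20, 30, 40, 50)
  # exact linear data triggers lm's perfect-fit warning by construction
  r <- suppressWarnings(agreement_model(x, x))
  expect_equal(r$slope, 1)
  expect_equal(r$intercept, 0, tolerance = 1e-12)
  expect_equal(r$r_squared, 1)

  # software = 2 * manual: regressing manual on software halves the slope
  r2 <- suppressWarnings(agreement_model(x, 2 * x))
  expect_equal(r2$slope, 0.5)

  # textbook closed forms on random data
  set.seed(6)
  man <- rnorm(30, 100, 20)
  soft <- 0.9 * man + rnorm(30, 0, 5)
  r3 <- agreement_model(man, soft)
  expect_equal(r3$slope, cov(soft, man) / var(soft), tolerance = 1e-12)
  expect_equal(r3$r_squared, cor(man, soft)^2, tolerance = 1e-12)
  expect_equal(r3$std_beta, cor(man, soft), tolerance = 1e-12)
  expect_equal(r3$df, 28L)

  expect_error(agreement_model(x, rep(1, 5)), "zero variance")
})

test_that("agreement CIs cover the truth across seeded simulations", {
  # regime of the manual-vs-software validation: slope near 1, negative
  # intercept, count noise
  hits_slope <- logical(100)
  hits_int <- logical(100)
  for (s in 1:100) {
    set.seed(700 + s)
    software <- runif(20, 500, 2500)
    manual <- -90 + 1.03 * software + rnorm(20, 0, 30)
    r <- agreement_model(manual, software)
    hits_slope[s] <- r$slope_ci[1] <= 1.03 && 1.03 <= r$slope_ci[2]
    hits_int[s] <- r$intercept_ci[1] <= -90 && -90 <= r$intercept_ci[2]
  }
  expect_gte(mean(hits_slope), 0.90)
  expect_gte(mean(hits_int), 0.90)
})

test_that("relative difference reports raw and rounded percentages", {
  r <- relative_difference(25125, 25693)
  expect_equal(r$rounded_percent, 2)
  expect_equal(r$percent, 100 * 568 / 25125)
  expect_equal(relative_difference(100, 100)$percent, 0)
  expect_equal(relative_difference(200, 150)$percent, 25)
  expect_error(relative_difference(0, 5), "> 0")
})

test_that("significance stars use the conventional thresholds", {
  expect_equal(significance_stars(c(0.0005, 0.005, 0.03, 0.2)),
               c("***", "**", "*", "ns"))
})
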