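test_that("sample ACF matches hand-computed values and affine invariance", {
  a <- sample_acf(c(1, 2, 3, 4), 3)
  expect_equal(a$rho, c(0.25, -0.30, -0.45))
  expect_equal(a$gamma0, 1.25)
  expect_equal(a$n, 4)

  set.seed(5)
  x <- rnorm(40)
  expect_equal(sample_acf(3 * x + 10, 8)$rho, sample_acf(x, 8)$rho)
  # agrees with the standard library estimate of the same quantity
  expect_equal(sample_acf(x, 8)$rho,
               as.numeric(acf(x, lag.max = 8, plot = FALSE)$acf)[-1],
               tolerance = 1e-12)

  expect_error(sample_acf(rep(2, 10), 3), "degenerate")
  expect_error(sample_acf(1:4, 4), "max_lag")
})

test_that("Yule threshold and flags follow the Bartlett bound", {
  set.seed(6)
  x <- rnorm(100)
  a <- sample_acf(x, 20)
  y <- yule_test(a, alpha = 0.05)
  expect_equal(y$threshold, 0.19600, tolerance = 1e-4)
  expect_equal(y$significant, abs(a$rho) > y$threshold)

  # strongly correlated series flags low lags; max lag reported in window
  ar <- as.numeric(arima.sim(list(ar = 0.8), n = 400))
  ya <- yule_test(sample_acf(ar, 40))
  expect_gt(ya$max_significant_lag, 0)
  expect_true(ya$significant[1])

  # a series with no correlation beyond the bound reports lag 0
  flat <- sample_acf(sin(1:1000) * 1e-8 + rep(c(1, 2), 500), 10)
  if (!any(abs(flat$rho) > yule_test(flat)$threshold))
    expect_equal(yule_test(flat)$max_significant_lag, 0L)
})

test_that("Ljung-Box matches the hand formula and the library oracle", {
  lb <- ljung_box(sample_acf(c(1, 2, 3, 4), 3), m = 1)
  expect_equal(lb$Q, 0.5)
  expect_equal(lb$p_value, 0.4795, tolerance = 1e-4)

  set.seed(7)
  for (i in 1:10) {
    x <- rnorm(sample(30:80, 1))
    m <- sample(5:10, 1)
    lb <- ljung_box(sample_acf(x, m), m = m)
    bx <- Box.test(x, lag = m, type = "Ljung-Box")
    expect_equal(lb$Q, as.numeric(bx$statistic), tolerance = 1e-12)
    expect_equal(lb$p_value, bx$p.value, tolerance = 1e-12)
  }
  expect_error(ljung_box(sample_acf(1:10 + rnorm(10), 9), m = 10), "smaller")
})

test_that("Bonferroni rejects at alpha over the family size", {
  expect_true(bonferroni_adjust(0.001, alpha = 0.05, N = 28))
  expect_false(bonferroni_adjust(0.01, alpha = 0.05, N = 28))
  expect_equal(attr(bonferroni_adjust(0.2, N = 1), "cutoff"), 0.05)
  expect_equal(as.logical(bonferroni_adjust(c(0.01, 0.04, 0.9), N = 1)),
               c(TRUE, TRUE, FALSE))
})

test_that("variance ratio reduces to its closed forms", {
  expect_equal(variance_ratio(rep(0, 10), n = 50)$R, 1)

  # constant-rho closed form R = 1 + rho * (n - 1), any (rho, n)
  set.seed(8)
  for (i in 1:25) {
    n <- sample(3:200, 1)
    rho <- runif(1, -1 / (n - 1), 1)   # keep R non-degenerate
    expect_equal(variance_ratio_constant(rho, n)$R, 1 + rho * (n - 1),
                 tolerance = 1e-12)
  }

  # single-lag form R = 1 + 2 * (1 - k/n) * rho
  expect_equal(variance_ratio_single(0.5, lag = 20, n = 80)$R, 7 / 4)
  expect_error(variance_ratio_single(0.5, lag = 80, n = 80), "smaller than n")

  # monotone increasing in each rho_k
  base <- rep(0.1, 5)
  R0 <- variance_ratio(base, n = 40)$R
  for (k in 1:5) {
    bumped <- base; bumped[k] <- base[k] + 0.05
    expect_gt(variance_ratio(bumped, n = 40)$R, R0)
  }
})

test_that("variance ratio from an ACF respects the lag-selection mode", {
  set.seed(9)
  x <- as.numeric(arima.sim(list(ar = 0.7), n = 300))
  a <- sample_acf(x, 40)
  sig <- variance_ratio_from_acf(a, mode = "significant")
  all_ <- variance_ratio_from_acf(a, mode = "all")
  keep <- yule_test(a)$significant
  expect_equal(sig$R, 1 + 2 * sum((1 - a$lags[keep] / a$n) * a$rho[keep]))
  expect_equal(all_$R, 1 + 2 * sum((1 - a$lags / a$n) * a$rho))
  expect_equal(sig$mode, "significant")
  expect_equal(sig$var_corrected / sig$var_iid, sig$R)
})

test_that("Grubbs screen flags a gross outlier and spares clean samples", {
  x <- c(1, 1.1, 0.9, 10)
  g <- grubbs_test(x)
  # independent critical value from the t-quantile formula
  tq <- qt(0.05 / (2 * 4), df = 2, lower.tail = FALSE)
  crit <- (3 / 2) * sqrt(tq^2 / (2 + tq^2))
  expect_equal(g$critical, crit)
  expect_equal(g$G, max(abs(x - mean(x))) / sd(x))
  expect_true(g$is_outlier)
  expect_equal(g$outlier_index, 4L)

  expect_false(grubbs_test(c(-1, 0, 1))$is_outlier)
  expect_error(grubbs_test(rep(3, 5)), "degenerate")

  # iterative mode can flag more; default flags at most one
  y <- c(rnorm(20, 0, 0.1), 5, 8)
  expect_lte(length(grubbs_test(y)$outlier_index), 1)
  expect_gte(length(grubbs_test(y, iterative = TRUE)$outlier_index),
             length(grubbs_test(y)$outlier_index))
})

test_that("dependence report bundles consistent components", {
  set.seed(10)
  x <- as.numeric(arima.sim(list(ar = 0.6), n = 120)) + 20
  rep_ <- dependence_report(x, max_lag = 40)
  expect_equal(rep_$n, 120)
  expect_equal(length(rep_$acf$rho), 40)
  expect_equal(rep_$ljung_box$m, 40)
  expect_lt(rep_$ljung_box$p_value, 0.05)   # strong AR must be detected
  expect_gt(rep_$variance_ratio$R, 1)       # positive correlation inflates

  # short series caps the lag window at n - 1
  short <- dependence_report(rnorm(12), max_lag = 40)
  expect_equal(short$ljung_box$m, 11)
})
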