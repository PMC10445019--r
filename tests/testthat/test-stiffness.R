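test_that("leg compression combines vertical excursion and horizontal sweep", {
  s0 <- toy_stance(rep(0.2, 3), rep(1.0, 3), rep(100, 3))
  expect_equal(leg_compression(s0, l0 = 1), 0)

  sv <- toy_stance(rep(0, 3), c(1.0, 0.96, 1.0), rep(100, 3))
  expect_equal(leg_compression(sv, l0 = 1), 0.04)

  sb <- toy_stance(c(-0.15, 0, 0.15), c(1.0, 0.95, 1.0), rep(100, 3))
  expect_equal(leg_compression(sb, l0 = 1),
               0.05 + 1 * (1 - sqrt(1 - 0.15^2)))
  expect_equal(leg_compression(sb, l0 = 1), 0.061314, tolerance = 1e-5)

  swide <- toy_stance(c(-1.5, 1.5), c(1, 1), c(1, 1))
  expect_error(leg_compression(swide, l0 = 1), "radicand")
})

test_that("compression properties: lower bound and monotonicity in the sweep", {
  set.seed(2)
  for (i in 1:25) {
    dy <- runif(1, 0, 0.2); dx <- runif(1, 0, 1.2)
    s <- toy_stance(c(0, dx / 2, dx), c(1, 1 - dy, 1), rep(1, 3))
    dL <- leg_compression(s, l0 = 1)
    expect_gte(dL, dy)
    if (dx == 0) expect_equal(dL, dy)
    s_wider <- toy_stance(c(0, dx / 2, dx + 0.1), c(1, 1 - dy, 1), rep(1, 3))
    expect_gt(leg_compression(s_wider, l0 = 1), dL)
  }
})

test_that("peak-force stiffness is the weight-corrected force over compression", {
  # engineered stance: dL = 0.06 m, F at min(y) = 1500 N
  s <- toy_stance(rep(0, 3), c(1.0, 0.94, 1.0), c(200, 1500, 200))
  expect_equal(as.numeric(k_max(s, l0 = 1, mass = 70, weight_correction = "none")),
               1500 / 0.06)
  expect_equal(as.numeric(k_max(s, l0 = 1, mass = 70)),   # default: subtract
               (1500 - 70 * 9.81) / 0.06)
  expect_equal(as.numeric(k_max(s, l0 = 1, mass = 70, weight_correction = "add")),
               (1500 + 70 * 9.81) / 0.06)

  sflat <- toy_stance(rep(0, 3), rep(1, 3), c(1, 2, 1))
  expect_error(k_max(sflat, l0 = 1, mass = 70), "zero leg compression")

  sedge <- toy_stance(rep(0, 3), c(0.94, 0.96, 1.0), c(1500, 800, 100))
  expect_warning(k_max(sedge, l0 = 1, mass = 70), "boundary")
})

test_that("no-intercept least squares matches closed form and brute force", {
  # p = l0 - y when x = 0, so l0 = 3, y = (2, 1) gives p = (1, 2)
  s <- toy_stance(c(0, 0), c(2, 1), F_y = c(2, 6))
  expect_equal(k_ols_noweight(s, l0 = 3, mass = 1, foot = "none"), 14 / 5)

  # exact linear response recovers the coefficient
  sc <- toy_stance(c(0, 0, 0), c(2.5, 2, 1.5), F_y = 7 * c(0.5, 1, 1.5))
  expect_equal(k_ols_noweight(sc, l0 = 3, mass = 1, foot = "none"), 7)

  # orthogonal response gives exactly zero
  so <- toy_stance(c(0, 0), c(2, 1), F_y = c(2, -1))
  expect_equal(k_ols_noweight(so, l0 = 3, mass = 1, foot = "none"), 0)

  # brute-force 1-D grid minimiser agrees
  set.seed(3)
  s3 <- toy_stance(rep(0, 5), runif(5, 0.9, 0.99), runif(5, 100, 2000))
  k_hat <- k_ols_noweight(s3, l0 = 1, mass = 70, foot = "none")
  p <- 1 - s3$y
  rss <- function(k) sum((s3$F_y - k * p)^2)
  grid <- seq(0.5 * k_hat, 1.5 * k_hat, length.out = 10001)
  k1 <- grid[which.min(vapply(grid, rss, numeric(1)))]
  grid2 <- seq(k1 - 2 * diff(grid[1:2]), k1 + 2 * diff(grid[1:2]),
               length.out = 10001)
  k2 <- grid2[which.min(vapply(grid2, rss, numeric(1)))]
  expect_equal(k_hat, k2, tolerance = 1e-6)
})

test_that("weight term shifts the slope by m*g*sum(p)/sum(p^2)", {
  s <- toy_stance(rep(0, 4), c(0.99, 0.95, 0.93, 0.97), c(500, 1500, 1800, 900))
  p <- 1 - s$y
  expect_equal(k_ols(s, l0 = 1, mass = 70, foot = "none") -
                 k_ols_noweight(s, l0 = 1, mass = 70, foot = "none"),
               70 * 9.81 * sum(p) / sum(p^2))
})

test_that("scaling the force scales k_ols and leaves the series ACF unchanged", {
  tr <- noiseless_trial(n_strides = 8)
  strides <- extract_strides(tr$recording)
  meta <- tr$recording$subject
  k1 <- vapply(strides, k_ols_noweight, numeric(1), l0 = meta$l0,
               mass = meta$mass)
  strides2 <- lapply(strides, function(s) { s$F_y <- 3 * s$F_y; s })
  k2 <- vapply(strides2, k_ols_noweight, numeric(1), l0 = meta$l0,
               mass = meta$mass)
  expect_equal(k2, 3 * k1, tolerance = 1e-9)

  # affine change of a series never moves its sample ACF
  set.seed(4)
  x <- rnorm(60)
  expect_equal(sample_acf(5 * x - 2, 10)$rho, sample_acf(x, 10)$rho)
})

test_that("noiseless SLIP strides recover the injected stiffness within 1%", {
  tr <- noiseless_trial(n_strides = 5, k = 20000)
  strides <- extract_strides(tr$recording)
  meta <- tr$recording$subject
  k_hat <- vapply(strides, k_ols_noweight, numeric(1), l0 = meta$l0,
                  mass = meta$mass)
  expect_true(all(abs(k_hat - 20000) / 20000 < 0.01))
})

test_that("k_max increases monotonically with the injected stiffness", {
  means <- vapply(c(10000, 15000, 20000, 25000), function(k) {
    tr <- noiseless_trial(n_strides = 3, k = k)
    strides <- extract_strides(tr$recording)
    meta <- tr$recording$subject
    mean(vapply(strides, function(s)
      as.numeric(k_max(s, meta$l0, meta$mass)), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("series assembly keeps order and drops undefined strides with a gap", {
  tr <- noiseless_trial(n_strides = 6)
  strides <- extract_strides(tr$recording)
  meta <- tr$recording$subject
  ser <- stiffness_series(strides, meta, "kols_noweight", velocity = 2.5)
  expect_length(ser$k, 6)
  expect_equal(ser$stride_index, 0:5)

  strides[[3]] <- toy_stance(rep(0, 3), rep(1, 3), c(1, 2, 1), stride_index = 2)
  ser2 <- suppressMessages(
    stiffness_series(strides, meta, "kmax", velocity = 2.5))
  expect_length(ser2$k, 5)
  expect_false(2L %in% ser2$stride_index)

  bad <- list(toy_stance(rep(0, 3), rep(1, 3), c(1, 2, 1)))
  expect_error(suppressMessages(stiffness_series(bad, meta, "kmax")),
               "empty stiffness series")
})

test_that("estimators track injected stiffness across a noisy AR trial", {
  proc <- stiffness_process_spec(20000, 0.6, 1000, n_strides = 60, seed = 12)
  tr <- assemble_trial(proc, slip_params(), noise_spec(0.001, 5, 12), v = 2.5)
  strides <- suppressMessages(
    extract_strides(tr$recording, threshold = 10, min_samples = 10))
  meta <- tr$recording$subject
  for (m in c("kols", "kols_noweight")) {
    ser <- stiffness_series(strides, meta, m, velocity = 2.5)
    expect_gt(cor(tr$true_k, ser$k, method = "spearman"), 0.95)
  }
  km <- stiffness_series(strides, meta, "kmax", velocity = 2.5)
  expect_gt(cor(tr$true_k, km$k, method = "spearman"), 0.7)
})
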