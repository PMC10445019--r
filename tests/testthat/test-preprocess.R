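test_that("force downsampling keeps every other sample from frame 0", {
  expect_equal(downsample_forces(c(0, 5, 10, 15)), c(0, 10))
  expect_equal(downsample_forces(7), 7)
  F <- rnorm(600)
  expect_equal(downsample_forces(F), F[seq(1, 599, by = 2)])
  expect_error(downsample_forces(numeric(0)), "empty")
})

test_that("CoM is the unweighted six-marker mean, with symmetric recovery", {
  n <- 20
  s <- data.frame(time_s = (0:(n - 1)) / 150)
  base_x <- sin(1:n); base_y <- cos(1:n)
  for (ch in c("asis_L", "asis_R", "psis_L", "psis_R", "crest_L", "crest_R")) {
    s[[paste0(ch, "_x")]] <- base_x
    s[[paste0(ch, "_y")]] <- base_y
  }
  com <- compute_com(s)
  expect_equal(com$x, base_x)
  expect_equal(com$y, base_y)

  # offsets symmetric about the CoM cancel exactly
  s2 <- s
  s2$asis_L_x <- base_x + 0.1; s2$psis_R_x <- base_x - 0.1
  s2$crest_L_y <- base_y + 0.05; s2$crest_R_y <- base_y - 0.05
  com2 <- compute_com(s2)
  expect_equal(com2$x, base_x)
  expect_equal(com2$y, base_y)
})

test_that("CoM gap handling interpolates short NA runs and rejects long ones", {
  n <- 30
  s <- data.frame(time_s = (0:(n - 1)) / 150)
  for (ch in c("asis_L", "asis_R", "psis_L", "psis_R", "crest_L", "crest_R")) {
    s[[paste0(ch, "_x")]] <- as.numeric(1:n)
    s[[paste0(ch, "_y")]] <- rep(1, n)
  }
  s$asis_L_x[10:12] <- NA
  expect_message(com <- compute_com(s, max_gap = 5), "interpolated")
  expect_equal(com$x, as.numeric(1:n))  # linear gap in a linear channel
  s$asis_L_x[10:20] <- NA
  expect_error(compute_com(s, max_gap = 5), "gap longer")
  expect_error(compute_com(s[, -2]), "asis_L_x")
})

test_that("recentring shifts x by the belt displacement", {
  rc <- recentre(c(0, 0, 0), c(1, 1, 1), t = c(0, 1, 2), v = 1)
  expect_equal(rc$x, c(0, 1, 2))
  expect_equal(rc$y, c(1, 1, 1))
  rc0 <- recentre(c(1, 2), c(3, 4), t = c(0, 1), v = 0)
  expect_equal(rc0$x, c(1, 2))
  rcv <- recentre(c(0, 0), c(1, 1), t = c(0, 1), v = 2, mode = "verbatim")
  expect_equal(rcv$y, c(1, 3))
  expect_error(recentre(1:3, 1:2, 1:3, 1), "equal length")
})

test_that("stance detection returns maximal positive runs as half-open intervals", {
  F <- c(0, 0, 10, 20, 10, 0, 0, 5, 0)
  expect_equal(detect_stances(F), list(c(2L, 5L), c(7L, 8L)))
  expect_equal(suppressMessages(detect_stances(F, min_samples = 2)),
               list(c(2L, 5L)))
  expect_equal(detect_stances(rep(0, 10)), list())

  # intervals reconstruct exactly the above-threshold samples
  set.seed(1)
  for (rep in 1:20) {
    F <- pmax(rnorm(50), 0) * rbinom(50, 1, 0.6)
    iv <- detect_stances(F, threshold = 0)
    covered <- unlist(lapply(iv, function(i) (i[1] + 1):i[2]))
    expect_equal(sort(covered), which(F > 0))
    if (length(iv) > 1) {
      starts <- vapply(iv, `[`, integer(1), 1)
      ends <- vapply(iv, `[`, integer(1), 2)
      expect_true(all(diff(starts) > 0))
      expect_true(all(starts[-1] >= ends[-length(ends)]))
    }
  }
})

test_that("trial writer and reader round-trip bit-exactly", {
  tr <- noiseless_trial(n_strides = 3)
  dir <- withr::local_tempdir()
  paths <- write_trial(tr, dir, "t1")
  rec <- read_trial(paths[["markers"]], paths[["force"]],
                    tr$recording$subject, tr$recording$velocity)
  expect_identical(rec$markers$asis_L_x, tr$recording$markers$asis_L_x)
  expect_identical(rec$force$Fy_N, tr$recording$force$Fy_N)

  # re-extracting from the re-read trial gives identical stance phases
  s1 <- extract_strides(tr$recording)
  s2 <- extract_strides(rec)
  expect_identical(s1, s2)

  # missing required channel is named in the error
  m2 <- tr$recording$markers
  m2$crest_L_x <- NULL
  expect_error(trial_recording(tr$recording$subject, 2.5, m2,
                               tr$recording$force),
               "crest_L_x")
})

test_that("stride extraction recovers the generator's stance structure", {
  tr <- noiseless_trial(n_strides = 20)
  strides <- extract_strides(tr$recording)
  expect_length(strides, 20)
  expect_equal(lapply(strides, function(s) s$interval),
               lapply(tr$true_stance_intervals, interval_to_marker_clock))
  idx <- vapply(strides, function(s) s$stride_index, integer(1))
  expect_equal(idx, 0:19)

  # CoM recovery: recentred y equals generator CoM height exactly
  com <- compute_com(tr$recording$markers)
  expect_lt(max(abs(com$y - tr$true_com_world$y)), 1e-12)
})

test_that("a trial truncated mid-stance drops the partial stance", {
  tr <- noiseless_trial(n_strides = 4)
  rec <- tr$recording
  iv <- tr$true_stance_intervals[[4]]
  cut_f <- iv[1] + 3                      # inside the final stance
  cut_m <- ceiling(cut_f / 2)
  rec$markers <- rec$markers[seq_len(cut_m), ]
  rec$force <- rec$force[seq_len(2 * cut_m - 1), ]
  expect_message(strides <- extract_strides(rec), "partial stance")
  expect_length(strides, 3)
  expect_equal(attr(strides, "n_truncated"), 1)
})

test_that("noisy stance boundaries stay within one sample of ground truth", {
  proc <- stiffness_process_spec(20000, numeric(), 0, n_strides = 10, seed = 4)
  tr <- assemble_trial(proc, slip_params(), noise_spec(0.001, 5, 4), v = 2.5)
  strides <- suppressMessages(
    extract_strides(tr$recording, threshold = 10, min_samples = 10))
  expect_length(strides, 10)
  err <- mapply(function(s, iv) max(abs(s$interval - interval_to_marker_clock(iv))),
                strides, tr$true_stance_intervals)
  expect_true(all(err <= 1))
})
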