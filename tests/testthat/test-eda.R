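test_that("LOF artifact scan flags bursts, not stationary noise", {
  # stationary Gaussian EMG: few windows flagged
  set.seed(21)
  fprop <- vapply(1:5, function(s) {
    ee <- simulate_eda_emg(sim_config(seed = 20 + s, duration_s = 200))
    w <- detect_motion_windows(ee$emg)
    mean(w$window_info$flagged)
  }, numeric(1))
  expect_lt(mean(fprop), 0.05)
  # a 5 s burst at gain 10: every overlapping window flagged, >= 90% coverage
  ee <- simulate_eda_emg(sim_config(seed = 30, duration_s = 200,
                                    artifact_windows = tibble::tibble(
                                      start_s = 80, duration_s = 5, gain = 10)))
  w <- detect_motion_windows(ee$emg)
  wi <- w$window_info
  overl <- wi$start_s < 85 & wi$end_s > 80
  expect_true(all(wi$flagged[overl]))
  ov <- sum(pmax(0, pmin(w$intervals$end_s, 85) - pmax(w$intervals$start_s, 80)))
  expect_gte(ov / 5, 0.9)
})

test_that("degenerate EMG inputs are handled", {
  t <- seq(0, 60, by = 0.01)
  w <- detect_motion_windows(channel(t, rep(3, length(t)), "EMG", 100))
  expect_equal(nrow(w$intervals), 0)
  expect_match(w$note, "constant")
  w2 <- detect_motion_windows(NULL)
  expect_equal(nrow(w2$intervals), 0)
  expect_match(w2$note, "absent")
})

test_that("EDA cleaning preserves constants and repairs contaminated windows", {
  fs <- 32
  t <- seq(0, 120, by = 1 / fs)
  const <- channel(t, rep(5, length(t)), "EDA", fs)
  out <- clean_eda(const, NULL)
  expect_equal(out$channel$value, rep(5, length(t)), tolerance = 1e-9)
  expect_true(out$acceptable)
  # a 20 uS spike inside a flagged window interpolates back to the constant
  x <- rep(5, length(t)); x[t >= 60 & t <= 62] <- 20
  win <- tibble::tibble(start_s = 59.5, end_s = 62.5)
  rep5 <- clean_eda(channel(t, x, "EDA", fs), win)
  expect_lt(max(abs(rep5$channel$value - 5)), 0.1)
  # interpolation never leaves the range of the neighboring clean samples
  expect_gte(min(rep5$channel$value), 5 - 1e-6)
  expect_lte(max(rep5$channel$value), 20 + 1e-6)
  # windows covering most of the channel are unacceptable
  big <- tibble::tibble(start_s = 0, end_s = 100)
  expect_false(clean_eda(channel(t, x, "EDA", fs), big)$acceptable)
})

test_that("slow EDA oscillations pass the cleaning filters nearly unchanged", {
  fs <- 32
  t <- seq(0, 300, by = 1 / fs)
  x <- 5 + 2 * sin(2 * pi * 0.02 * t)
  out <- clean_eda(channel(t, x, "EDA", fs), NULL)
  err <- sqrt(mean((out$channel$value - x)^2)) / sqrt(mean((x - mean(x))^2))
  expect_lt(err, 0.05)
})

test_that("quality index counts range and rate violations as specified", {
  fs <- 32
  t <- seq(0, 600 - 1 / fs, by = 1 / fs)
  n <- length(t)
  q1 <- eda_quality_index(channel(t, rep(5, n), "EDA", fs))
  expect_equal(q1$qi, 100)
  expect_true(q1$acceptable)
  q2 <- eda_quality_index(channel(t, rep(0.01, n), "EDA", fs))
  expect_equal(q2$qi, 0)
  expect_false(q2$acceptable)
  # 49% out of range + the jump neighborhood: qi just above 50, acceptable
  v <- ifelse(seq_len(n) <= 0.49 * n, 0.01, 5)
  q3 <- eda_quality_index(channel(t, v, "EDA", fs))
  expect_gt(q3$qi, 50)
  expect_lt(q3$qi, 52)
  expect_true(q3$acceptable)
  # verdict flips below 50
  v4 <- ifelse(seq_len(n) <= 0.51 * n, 0.01, 5)
  q4 <- eda_quality_index(channel(t, v4, "EDA", fs))
  expect_lt(q4$qi, 50)
  expect_false(q4$acceptable)
})

test_that("quality index is reversal-invariant and monotone in violations", {
  fs <- 32
  t <- seq(0, 100, by = 1 / fs)
  set.seed(7)
  x <- 5 + cumsum(rnorm(length(t), 0, 0.01))
  x[2000:2100] <- 0.01
  qi_f <- eda_quality_index(channel(t, x, "EDA", fs))$qi
  qi_r <- eda_quality_index(channel(t, rev(x), "EDA", fs))$qi
  expect_equal(qi_f, qi_r)
  # pushing more samples out of range never raises qi
  qs <- vapply(c(0, 500, 1500, 3000), function(k) {
    y <- x
    if (k > 0) y[seq_len(k)] <- 0.01
    eda_quality_index(channel(t, y, "EDA", fs))$qi
  }, numeric(1))
  expect_true(all(diff(qs) <= 1e-9))
})

test_that("tonic series averages the slow component over 2-minute windows", {
  fs <- 32
  t <- seq(0, 600, by = 1 / fs)
  expect_equal(tonic_series(channel(t, rep(3, length(t)), "EDA", fs))$tonic_uS,
               rep(3, 5), tolerance = 1e-4)
  ramp <- tonic_series(channel(t, t / 60, "EDA", fs))
  expect_equal(ramp$tonic_uS, c(1, 3, 5, 7, 9), tolerance = 0.1)
  # simulated tonic + SCRs at the default rate: within 0.2 uS of truth
  cfg <- sim_config(seed = 31, duration_s = 600,
                    eda_tonic_trajectory = tibble::tibble(time_s = c(0, 600),
                                                          uS = c(4, 7)))
  ee <- simulate_eda_emg(cfg)
  cl <- clean_eda(ee$eda, NULL)
  ts <- tonic_series(cl$channel)
  true_means <- vapply(1:5, function(w) {
    tt <- seq((w - 1) * 120, w * 120, by = 0.1)
    mean(ee$truth$tonic_at(tt))
  }, numeric(1))
  expect_lt(max(abs(ts$tonic_uS - true_means)), 0.2)
})
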