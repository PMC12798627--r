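test_that("cleaning is linear at zero and respects the band edges", {
  fs <- 500
  t <- seq(0, 60, by = 1 / fs)
  zero <- clean_ecg(channel(t, rep(0, length(t)), "ECG", fs))
  expect_true(all(zero$channel$value == 0))
  expect_false(any(zero$mask))
  # 60 Hz powerline: strongly attenuated
  x60 <- sin(2 * pi * 60 * t)
  out60 <- clean_ecg(channel(t, x60, "ECG", fs))$channel$value
  expect_lt(sqrt(mean(out60^2)), 0.1 * sqrt(mean(x60^2)))
  # 10 Hz passband: preserved within 10%
  x10 <- 100 * sin(2 * pi * 10 * t)
  out10 <- clean_ecg(channel(t, x10, "ECG", fs))$channel$value
  expect_lt(abs(sqrt(mean(out10^2)) / sqrt(mean(x10^2)) - 1), 0.1)
  expect_error(clean_ecg(channel(t[1:100], x10[1:100], "ECG", 80)), "sampling rate")
})

test_that("the amplitude gate masks and interpolates offending samples", {
  fs <- 500
  t <- seq(0, 30, by = 1 / fs)
  x <- 100 * sin(2 * pi * 10 * t)
  # the gate applies to the filtered signal; a saturation episode has to
  # outlast the bandpass impulse response to exceed the threshold there
  x[t >= 10 & t <= 10.05] <- 3000
  cl <- clean_ecg(channel(t, x, "ECG", fs))
  expect_true(any(cl$mask))
  expect_lt(max(abs(cl$channel$value)), 1500 + 1e-9)
  expect_gt(cl$masked_fraction, 0)
  expect_true(cl$acceptable)
})

test_that("passband filtering is idempotent and zero-phase", {
  fs <- 500
  t <- seq(0, 30, by = 1 / fs)
  x <- 100 * sin(2 * pi * 10 * t) + 30 * sin(2 * pi * 25 * t)
  ch <- channel(t, x, "ECG", fs)
  once <- clean_ecg(ch)$channel
  twice <- clean_ecg(once)$channel
  expect_lt(abs(sqrt(mean(twice$value^2)) / sqrt(mean(once$value^2)) - 1), 0.02)
  # zero-phase: cross-correlation peak at lag 0
  cc <- ccf(once$value, x, lag.max = 25, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("baseline-wander verdict crosses at the configured peak-to-peak", {
  fs <- 250
  t <- seq(0, 120, by = 1 / fs)
  drift <- function(a) channel(t, a * sin(2 * pi * 0.1 * t), "ECG", fs)
  expect_equal(assess_ecg_acceptability(drift(0))$wander, 0, tolerance = 1e-6)
  expect_true(assess_ecg_acceptability(drift(100))$acceptable)
  a840 <- assess_ecg_acceptability(drift(840))
  a900 <- assess_ecg_acceptability(drift(900))
  expect_true(a840$acceptable)
  expect_false(a900$acceptable)
  expect_equal(a900$wander, 1800, tolerance = 0.01 * 1800)
  # monotone in drift amplitude
  amps <- c(100, 400, 700, 850, 1000, 1300)
  wander <- vapply(amps, function(a) assess_ecg_acceptability(drift(a))$wander,
                   numeric(1))
  expect_true(all(diff(wander) > 0))
})

test_that("R peaks are recovered on simulated ECG to a few milliseconds", {
  cfg <- sim_config(seed = 5, duration_s = 600, mean_hr_bpm = 60,
                    rr_modulation = tibble::tibble(freq_hz = 0.1, amplitude_s = 0.05),
                    rr_noise_sd_s = 0)
  e <- simulate_ecg(cfg)
  cl <- clean_ecg(e$channel)
  rp <- detect_r_peaks(cl$channel)
  expect_true(attr(rp, "acceptable"))
  expect_true(abs(nrow(rp) - length(e$truth$r_peaks_s)) <= 1)
  err <- vapply(e$truth$r_peaks_s, function(tp) min(abs(rp$time_s - tp)), numeric(1))
  expect_lt(max(err), 0.005)
  # recovered RR series tracks the modulated truth
  rr_det <- rr_intervals(rp)
  rr_true <- diff(e$truth$r_peaks_s)
  t_true <- (head(e$truth$r_peaks_s, -1) + tail(e$truth$r_peaks_s, -1)) / 2
  rr_interp <- approx(t_true, rr_true, rr_det$t_mid_s, rule = 2)$y
  expect_gt(cor(rr_det$rr_s, rr_interp), 0.95)
})

test_that("flat ECG yields no peaks and an unacceptable verdict", {
  t <- seq(0, 120, by = 1 / 250)
  rp <- detect_r_peaks(channel(t, rep(0, length(t)), "ECG", 250))
  expect_equal(nrow(rp), 0)
  expect_false(attr(rp, "acceptable"))
})

test_that("per-minute heart rate follows closed forms", {
  rp <- peaks_from_times(seq(0.5, 599.5, by = 1))
  hr <- heart_rate_series(rp, span_s = 600)
  expect_equal(nrow(hr), 10)
  expect_equal(hr$hr_bpm, rep(60, 10))
  # piecewise: RR 1 s for 5 min then 0.5 s
  rp2 <- peaks_from_times(c(seq(0.5, 300, by = 1), seq(300.5, 599.75, by = 0.5)))
  hr2 <- heart_rate_series(rp2, span_s = 600)
  expect_equal(hr2$hr_bpm[1:5], rep(60, 5), tolerance = 0.01)
  expect_equal(hr2$hr_bpm[6:10], rep(120, 5), tolerance = 0.01)
  # empty series: all windows missing
  hr3 <- heart_rate_series(peaks_from_times(numeric(0)), span_s = 600)
  expect_true(all(is.na(hr3$hr_bpm)))
  # per-minute recovery on a simulated session within 1 bpm
  cfg <- sim_config(seed = 6, duration_s = 600, mean_hr_bpm = 72)
  e <- simulate_ecg(cfg)
  rp4 <- detect_r_peaks(clean_ecg(e$channel)$channel)
  hr4 <- heart_rate_series(rp4, span_s = 600)
  rr_t <- diff(e$truth$r_peaks_s)
  mid <- (head(e$truth$r_peaks_s, -1) + tail(e$truth$r_peaks_s, -1)) / 2
  true_hr <- vapply(1:10, function(w) {
    sel <- mid >= (w - 1) * 60 & mid < w * 60
    60 / mean(rr_t[sel])
  }, numeric(1))
  expect_lt(max(abs(hr4$hr_bpm - true_hr)), 1)
})
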