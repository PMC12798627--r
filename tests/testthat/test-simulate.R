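test_that("4-7-8 pacing produces the arithmetic cycle count and spacing", {
  cfg <- sim_config(seed = 1, duration_s = 600, protocol = "breathwork_478",
                    breathwork_leadin_s = 0, cycle_jitter_sd = 0)
  r <- simulate_respiration(cfg)
  # floor(600 / 19) complete cycles, onsets 19 s apart
  expect_equal(nrow(r$truth$breaths), 31)
  expect_equal(diff(r$truth$breaths$inh_s), rep(19, 30))
  expect_equal(r$truth$breaths$exh_s - r$truth$breaths$inh_s, rep(11, 31))
})

test_that("free breathing at a constant rate yields rate x time onsets", {
  cfg <- sim_config(seed = 1, duration_s = 120, base_breath_rate_bpm = 15,
                    cycle_jitter_sd = 0)
  r <- simulate_respiration(cfg)
  expect_equal(nrow(r$truth$breaths), 30)
})

test_that("noiseless respiration is exactly periodic; seeds give bit-identical output", {
  cfg <- sim_config(seed = 4, duration_s = 60, base_breath_rate_bpm = 12,
                    cycle_jitter_sd = 0, noise_sd = list(ecg = 20, resp = 0,
                                                         eda = 0.01, emg = 10))
  r <- simulate_respiration(cfg)
  fs <- channel_fs(r$channel)
  period_samples <- 5 * fs  # 12 bpm = 5 s
  v <- head(r$channel$value, -1)  # final grid point starts an unrendered cycle
  expect_equal(v[seq_len(length(v) - period_samples)],
               v[-seq_len(period_samples)], tolerance = 1e-9)
  expect_identical(simulate_respiration(cfg)$channel, r$channel)
  s1 <- simulate_session(sim_config(seed = 9, duration_s = 60))
  s2 <- simulate_session(sim_config(seed = 9, duration_s = 60))
  expect_identical(s1$session$channels, s2$session$channels)
})

test_that("simulated ECG peak count matches heart rate and flags bad configs", {
  cfg <- sim_config(seed = 2, duration_s = 600, mean_hr_bpm = 60,
                    rr_modulation = tibble::tibble(freq_hz = numeric(),
                                                   amplitude_s = numeric()),
                    rr_noise_sd_s = 0)
  e <- simulate_ecg(cfg)
  expect_true(abs(length(e$truth$r_peaks_s) - 600) <= 1)
  # modulation amplitude exceeding the mean RR is rejected
  bad <- sim_config(seed = 2, mean_hr_bpm = 60,
                    rr_modulation = tibble::tibble(freq_hz = 0.1, amplitude_s = 1.5))
  expect_error(simulate_ecg(bad), "modulation amplitudes")
})

test_that("ground-truth RR spectrum peaks in the configured band", {
  cfg <- sim_config(seed = 3, duration_s = 600, mean_hr_bpm = 60,
                    rr_modulation = tibble::tibble(freq_hz = 0.1, amplitude_s = 0.05),
                    rr_noise_sd_s = 0)
  e <- simulate_ecg(cfg)
  rr <- diff(e$truth$r_peaks_s)
  tm <- (head(e$truth$r_peaks_s, -1) + tail(e$truth$r_peaks_s, -1)) / 2
  grid <- seq(min(tm), max(tm), by = 0.25)
  tach <- approx(tm, rr, grid)$y
  sp <- stats::spec.pgram(stats::ts(tach, frequency = 4), plot = FALSE,
                          detrend = TRUE, taper = 0)
  f_peak <- sp$freq[which.max(sp$spec)]
  expect_gt(f_peak, 0.04)
  expect_lt(f_peak, 0.15)
})

test_that("EDA generative identities hold", {
  # pure tonic ramp with everything else disabled reproduces the ramp
  cfg <- sim_config(seed = 5, duration_s = 120,
                    eda_tonic_trajectory = tibble::tibble(time_s = c(0, 120),
                                                          uS = c(2, 8)),
                    scr_rate_per_min = 0,
                    noise_sd = list(ecg = 20, resp = 0.05, eda = 0, emg = 10))
  ee <- simulate_eda_emg(cfg)
  expect_equal(ee$eda$value, 2 + ee$eda$time_s * 6 / 120, tolerance = 1e-12)
  # SCR Poisson mean: about rate x duration over seeds
  counts <- vapply(1:30, function(s) {
    cfg <- sim_config(seed = s, duration_s = 600, scr_rate_per_min = 4)
    length(simulate_eda_emg(cfg)$truth$scr_times_s)
  }, numeric(1))
  expect_gt(mean(counts), 40 - 5)
  expect_lt(mean(counts), 40 + 5)
  # fixed seed reproduces the count
  c1 <- length(simulate_eda_emg(sim_config(seed = 7))$truth$scr_times_s)
  c2 <- length(simulate_eda_emg(sim_config(seed = 7))$truth$scr_times_s)
  expect_identical(c1, c2)
})

test_that("EMG bursts scale variance by the squared gain and windows merge", {
  cfg <- sim_config(seed = 6, duration_s = 120,
                    artifact_windows = tibble::tibble(start_s = c(40, 43),
                                                      duration_s = c(5, 5),
                                                      gain = c(10, 10)))
  ee <- simulate_eda_emg(cfg)
  expect_equal(nrow(ee$truth$artifact_windows), 1)  # overlap merged
  emg <- ee$emg
  inside <- emg$time_s >= 40 & emg$time_s <= 45
  outside <- emg$time_s < 35 | emg$time_s > 55
  expect_gt(var(emg$value[inside]) / var(emg$value[outside]), 25)
})

test_that("a full session carries all modalities, markers and the designed contrast", {
  s <- simulate_session(sim_config(seed = 8, protocol = "breathwork_478"))
  expect_setequal(names(s$session$channels), c("ECG", "EDA", "EMG", "RESP"))
  expect_equal(s$session$markers$time_s, c(0, 600))
  expect_equal(s$session$stim, "Breathwork")
  gt <- breath_rate_series(ground_truth_breath_events(s$truth))
  # paced sessions drop from the lead-in rate to ~3.2 breaths/min
  expect_gt(gt$rates$rate_bpm[1], gt$rates$rate_bpm[5])
  r <- simulate_session(sim_config(seed = 8, protocol = "free_breathing"))
  gr <- breath_rate_series(ground_truth_breath_events(r$truth))
  expect_lt(max(gr$rates$rate_bpm) - min(gr$rates$rate_bpm), 1.01)
})

test_that("ground-truth-only breath path matches the rendered path", {
  cfg <- sim_config(seed = 10, protocol = "breathwork_478")
  a <- simulate_respiration(cfg)$truth$breaths$inh_s
  b <- simulate_breath_events(cfg)$breaths$inh_s
  expect_identical(a, b)
})

test_that("clean simulated EDA stays in the physiological range with qi 100", {
  ee <- simulate_eda_emg(sim_config(seed = 11, duration_s = 300))
  expect_true(all(ee$eda$value > 0.05 & ee$eda$value < 60))
  qi <- eda_quality_index(ee$eda)
  expect_equal(qi$qi, 100)
})
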