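# Shared fixture builders (everything is generated in code).

sine_channel <- function(freq_hz, fs, dur_s, amp = 1, modality = "RESP",
                         phase = 0, offset = 0) {
  t <- seq(0, dur_s, by = 1 / fs)
  channel(t, offset + amp * sin(2 * pi * freq_hz * t + phase), modality, fs)
}

# r_peak_series straight from times (bypasses detection)
peaks_from_times <- function(times) physiopipe:::new_r_peak_series(times)

# RR series with sinusoidal modulation, as ground-truth peak times
modulated_peaks <- function(dur_s, mean_rr = 1, f_mod = 0.1, a_mod = 0.05,
                            noise_sd = 0, seed = 1) {
  set.seed(seed)
  t <- 0.3
  out <- numeric(0)
  while (t < dur_s) {
    out <- c(out, t)
    rr <- mean_rr + a_mod * sin(2 * pi * f_mod * t) + rnorm(1, 0, noise_sd)
    t <- t + rr
  }
  peaks_from_times(out)
}

long_table <- function(Y, tech = NULL, stim = NULL) {
  n <- nrow(Y); k <- ncol(Y)
  if (is.null(tech)) tech <- rep("A", n)
  if (is.null(stim)) stim <- rep("B", n)
  tibble::tibble(
    participant = rep(sprintf("p%03d", seq_len(n)), times = k),
    timepoint = rep(seq_len(k), each = n),
    value = as.vector(Y),
    tech = rep(tech, times = k),
    stim = rep(stim, times = k)
  )
}
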