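#' HRV analysis parameters
#'
#' Spectral heart-rate-variability settings: the low-frequency band is
#' 0.04-0.15 Hz, the high-frequency band 0.15-0.4 Hz (the shared 0.15 Hz
#' boundary is assigned to HF), the RR tachogram is interpolated to a
#' uniform 4 Hz grid and linearly detrended, and the Welch estimate uses
#' 120 s Hann-tapered segments with 50% overlap — at least three averages
#' within a 5-minute segment while still resolving 0.04 Hz.
#'
#' @param lf_band,hf_band Band edges in Hz.
#' @param tachogram_rate_hz Uniform tachogram sampling rate.
#' @param welch_segment_s Welch segment length in seconds.
#' @param welch_overlap Segment overlap fraction.
#' @param min_rr Minimum number of RR intervals required in a segment.
#' @return List of class `hrv_params`.
#' @export
hrv_params <- function(lf_band = c(0.04, 0.15), hf_band = c(0.15, 0.4),
                       tachogram_rate_hz = 4, welch_segment_s = 120,
                       welch_overlap = 0.5, min_rr = 60) {
  stopifnot(lf_band[2] <= hf_band[1], tachogram_rate_hz > 2 * hf_band[2])
  structure(list(lf_band = lf_band, hf_band = hf_band,
                 tachogram_rate_hz = tachogram_rate_hz,
                 welch_segment_s = welch_segment_s,
                 welch_overlap = welch_overlap, min_rr = min_rr),
            class = c("hrv_params", "list"))
}

# Welch power spectral density: Hann-tapered, demeaned segments with the
# given overlap; one-sided density normalized so that its integral equals
# the signal variance (interior bins doubled).
welch_psd <- function(x, fs, seg_len, overlap = 0.5) {
  n <- length(x)
  seg_len <- min(as.integer(seg_len), n)
  step <- max(1L, as.integer(round(seg_len * (1 - overlap))))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, seg_len - 1) / (seg_len - 1))
  scale <- fs * sum(w^2)
  nf <- seg_len %/% 2L + 1L
  acc <- numeric(nf)
  for (i0 in starts) {
    seg <- x[i0:(i0 + seg_len - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(stats::fft(seg))[1:nf]^2 / scale
    acc <- acc + p
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist for even seg_len)
  dbl <- rep(2, nf); dbl[1] <- 1
  if (seg_len %% 2L == 0L) dbl[nf] <- 1
  tibble::tibble(freq_hz = (0:(nf - 1L)) * fs / seg_len, psd = psd * dbl)
}

# Integrate a PSD over [lo, hi); `include_hi` closes the upper edge.
band_power <- function(psd, lo, hi, include_hi = FALSE) {
  sel <- psd$freq_hz >= lo & (if (include_hi) psd$freq_hz <= hi else psd$freq_hz < hi)
  if (sum(sel) < 2L) return(0)
  trapz(psd$freq_hz[sel], psd$psd[sel])
}

#' LF and HF band power and their ratio for one segment
#'
#' Builds the RR tachogram at the interval midpoints, interpolates it to a
#' uniform grid, removes a linear trend, estimates the PSD by Welch's
#' method and integrates it over the LF (0.04-0.15 Hz) and HF (0.15-0.4 Hz)
#' bands; the LF/HF ratio indexes sympathovagal balance. Band powers are in
#' s^2 (tachogram variance units). Segments with too few RR intervals are
#' returned as missing; a zero HF power flags the ratio undefined.
#'
#' @param rp An `r_peak_series` (see [detect_r_peaks()]).
#' @param interval Two-element numeric: segment start and end in seconds.
#' @param params An [hrv_params()] list.
#' @param segment Label stored on the result row.
#' @return One-row tibble: `segment`, `lf_power`, `hf_power`,
#'   `lf_hf_ratio`, `n_rr`, `usable`.
#' @export
lf_hf <- function(rp, interval, params = hrv_params(), segment = "segment") {
  rr <- rr_intervals(rp)
  sel <- rr$t_mid_s >= interval[1] & rr$t_mid_s < interval[2]
  rr <- rr[sel, ]
  if (nrow(rr) < params$min_rr) {
    return(tibble::tibble(segment = segment, lf_power = NA_real_,
                          hf_power = NA_real_, lf_hf_ratio = NA_real_,
                          n_rr = nrow(rr), usable = FALSE))
  }
  fs <- params$tachogram_rate_hz
  grid <- seq(interval[1], interval[2], by = 1 / fs)
  tach <- stats::approx(rr$t_mid_s, rr$rr_s, xout = grid, rule = 2,
                        ties = "ordered")$y
  # linear detrend
  i <- seq_along(tach)
  fit <- stats::lm.fit(cbind(1, i), tach)
  tach <- fit$residuals
  psd <- welch_psd(tach, fs, seg_len = params$welch_segment_s * fs,
                   overlap = params$welch_overlap)
  lf <- band_power(psd, params$lf_band[1], params$lf_band[2], include_hi = FALSE)
  hf <- band_power(psd, params$hf_band[1], params$hf_band[2], include_hi = TRUE)
  ratio <- if (hf > 1e-12) lf / hf else NA_real_
  tibble::tibble(segment = segment, lf_power = lf, hf_power = hf,
                 lf_hf_ratio = ratio, n_rr = nrow(rr), usable = TRUE)
}

#' LF/HF for the first and last 5 minutes of a session
#'
#' Applies [lf_hf()] to the segments spanning 0-300 s and the final 300 s of
#' the session. Sessions shorter than 600 s report only the segments that
#' fit: the first segment needs at least 300 s of span, the last needs the
#' full 600 s.
#'
#' @param rp An `r_peak_series`.
#' @param span_s Session span in seconds.
#' @param params An [hrv_params()] list.
#' @return Tibble with up to two rows (`first_5min`, `last_5min`); segments
#'   that do not fit are present with `usable = FALSE`.
#' @export
hrv_first_last <- function(rp, span_s = 600, params = hrv_params()) {
  missing_row <- function(seg) tibble::tibble(segment = seg, lf_power = NA_real_,
                                              hf_power = NA_real_,
                                              lf_hf_ratio = NA_real_,
                                              n_rr = 0L, usable = FALSE)
  first <- if (span_s >= 300) lf_hf(rp, c(0, 300), params, "first_5min") else
    missing_row("first_5min")
  last <- if (span_s >= 600) lf_hf(rp, c(span_s - 300, span_s), params, "last_5min") else
    missing_row("last_5min")
  dplyr::bind_rows(first, last)
}

#' LF/HF computed directly on the ECG waveform (literal variant)
#'
#' A comparison path that integrates the Welch PSD of the raw cleaned ECG
#' waveform (decimated to the tachogram rate) over the same LF/HF bands.
#' Band power of the raw waveform at 0.04-0.4 Hz is dominated by baseline
#' residue rather than beat-to-beat variability, so the tachogram route
#' ([lf_hf()]) is the default analysis surface; this function exists to make
#' the two readings comparable.
#'
#' @param ch A cleaned ECG [channel()].
#' @param interval Two-element numeric: segment start and end in seconds.
#' @param params An [hrv_params()] list.
#' @param segment Label stored on the result row.
#' @return One-row tibble with the same columns as [lf_hf()].
#' @export
lf_hf_signal <- function(ch, interval, params = hrv_params(), segment = "segment") {
  stopifnot(is_channel(ch))
  sel <- ch$time_s >= interval[1] & ch$time_s < interval[2]
  if (sum(sel) < 10L) {
    return(tibble::tibble(segment = segment, lf_power = NA_real_,
                          hf_power = NA_real_, lf_hf_ratio = NA_real_,
                          n_rr = 0L, usable = FALSE))
  }
  fs <- params$tachogram_rate_hz
  grid <- seq(interval[1], interval[2], by = 1 / fs)
  x <- stats::approx(ch$time_s[sel], ch$value[sel], xout = grid, rule = 2,
                     ties = "ordered")$y
  i <- seq_along(x)
  x <- stats::lm.fit(cbind(1, i), x)$residuals
  psd <- welch_psd(x, fs, seg_len = params$welch_segment_s * fs,
                   overlap = params$welch_overlap)
  lf <- band_power(psd, params$lf_band[1], params$lf_band[2], include_hi = FALSE)
  hf <- band_power(psd, params$hf_band[1], params$hf_band[2], include_hi = TRUE)
  ratio <- if (hf > 1e-12) lf / hf else NA_real_
  tibble::tibble(segment = segment, lf_power = lf, hf_power = hf,
                 lf_hf_ratio = ratio, n_rr = NA_integer_, usable = TRUE)
}
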