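#' ECG processing parameters
#'
#' Defaults implement the cleaning rules used throughout the pipeline:
#' 60 Hz powerline notch, 0.5-45 Hz 4th-order Butterworth bandpass (applied
#' forward-backward, i.e. zero-phase), an amplitude gate at 1500 device
#' units ("mV" as printed by the recorder) applied after filtering, and a
#' baseline-wandering acceptability threshold of 1700 device units
#' peak-to-peak on the low-frequency baseline estimate.
#'
#' @param notch_hz Powerline frequency to notch out.
#' @param notch_q Quality factor of the second-order IIR notch.
#' @param bp_low_hz,bp_high_hz Bandpass corner frequencies.
#' @param bp_order Designed Butterworth prototype order (doubled in effect by
#'   the forward-backward application).
#' @param amp_threshold Absolute amplitude gate after filtering; exceeding
#'   samples are masked and linearly interpolated.
#' @param wander_threshold Peak-to-peak threshold on the baseline estimate
#'   above which the channel is unacceptable.
#' @param max_masked_fraction Channel marked unacceptable when more than this
#'   fraction of samples is amplitude-masked.
#' @return List of class `ecg_params`.
#' @export
ecg_params <- function(notch_hz = 60, notch_q = 30, bp_low_hz = 0.5,
                       bp_high_hz = 45, bp_order = 4, amp_threshold = 1500,
                       wander_threshold = 1700, max_masked_fraction = 0.5) {
  stopifnot(bp_low_hz > 0, bp_low_hz < bp_high_hz, amp_threshold > 0,
            wander_threshold > 0)
  structure(list(notch_hz = notch_hz, notch_q = notch_q, bp_low_hz = bp_low_hz,
                 bp_high_hz = bp_high_hz, bp_order = bp_order,
                 amp_threshold = amp_threshold,
                 wander_threshold = wander_threshold,
                 max_masked_fraction = max_masked_fraction),
            class = c("ecg_params", "list"))
}

#' Clean an ECG channel
#'
#' Sanitizes the channel (leading/trailing non-finite samples dropped,
#' interior ones linearly interpolated), removes powerline interference with
#' a zero-phase IIR notch, bandpasses with a zero-phase 4th-order
#' Butterworth, then masks samples whose filtered absolute amplitude exceeds
#' the gate and replaces them by linear interpolation, preserving the
#' uniform time grid.
#'
#' @param ch An ECG [channel()].
#' @param params An [ecg_params()] list.
#' @return List of class `ecg_clean` with elements `channel` (cleaned),
#'   `mask` (logical, amplitude-rejected samples), `masked_fraction`, and
#'   `acceptable` (`FALSE` when more than half the samples were masked).
#' @export
clean_ecg <- function(ch, params = ecg_params()) {
  stopifnot(is_channel(ch))
  fs <- channel_fs(ch)
  if (fs <= 90) stop("unsupported ECG sampling rate (", fs, " Hz): need fs > 90 Hz")
  san <- sanitize_samples(ch$time_s, ch$value)
  x <- notch_filtfilt(san$value, fs, params$notch_hz, params$notch_q)
  x <- butter_filtfilt(x, fs, c(params$bp_low_hz, params$bp_high_hz),
                       type = "pass", order = params$bp_order)
  mask <- abs(x) > params$amp_threshold
  masked_fraction <- mean(mask)
  if (any(mask) && !all(mask)) {
    x[mask] <- stats::approx(san$time_s[!mask], x[!mask], xout = san$time_s[mask],
                             rule = 2, ties = "ordered")$y
  }
  structure(
    list(channel = rebuild_channel(ch, san$time_s, x),
         mask = mask,
         masked_fraction = masked_fraction,
         acceptable = masked_fraction <= params$max_masked_fraction,
         n_interpolated = san$n_interpolated),
    class = "ecg_clean"
  )
}

#' Assess ECG acceptability from baseline wandering
#'
#' Baseline wandering is a low-frequency artifact, so it is measured on a
#' low-frequency baseline estimate: a zero-phase 0.5 Hz low-pass of the
#' sanitized (pre-bandpass) signal. The wander value is that baseline's
#' peak-to-peak amplitude; the channel is unacceptable when it exceeds the
#' 1700-unit threshold.
#'
#' @param ch The raw (or sanitized) ECG [channel()], before bandpassing.
#' @param params An [ecg_params()] list.
#' @return List with `wander` (peak-to-peak of the baseline estimate, device
#'   units) and `acceptable` (logical).
#' @export
assess_ecg_acceptability <- function(ch, params = ecg_params()) {
  stopifnot(is_channel(ch))
  if (nrow(ch) == 0L) stop("empty ECG channel")
  fs <- channel_fs(ch)
  san <- sanitize_samples(ch$time_s, ch$value)
  baseline <- butter_filtfilt(san$value, fs, params$bp_low_hz, type = "low", order = 4)
  wander <- diff(range(baseline))
  list(wander = wander, acceptable = wander <= params$wander_threshold)
}

#' Detect R peaks in a cleaned ECG channel
#'
#' Local-maximum detection above an adaptive threshold: the squared
#' derivative of the signal is smoothed over 150 ms; a blockwise (2 s)
#' running maximum of that energy sets the detection threshold at half the
#' local maximum. Candidate regions above threshold contribute the sample
#' where the signal is largest, a 250 ms refractory period is enforced, and
#' physiologically impossible short RR intervals (< 0.25 s) are repaired by
#' dropping the smaller of the two peaks.
#'
#' @param ch A cleaned, acceptable ECG [channel()].
#' @param refractory_s Minimum distance between peaks.
#' @return Tibble of class `r_peak_series` with column `time_s`; attribute
#'   `acceptable` is `FALSE` when fewer than 10 peaks were found in a
#'   channel of at least 60 s.
#' @export
detect_r_peaks <- function(ch, refractory_s = 0.25) {
  stopifnot(is_channel(ch))
  fs <- channel_fs(ch)
  x <- ch$value
  n <- length(x)
  energy <- moving_average(c(0, diff(x))^2, round(0.15 * fs))
  # blockwise 2 s adaptive threshold: half the max of own + neighbour blocks
  blk <- pmax(1L, as.integer(round(2 * fs)))
  nblk <- ceiling(n / blk)
  bid <- rep(seq_len(nblk), each = blk)[seq_len(n)]
  bmax <- as.vector(tapply(energy, bid, max))
  bmax_sm <- pmax(bmax, c(bmax[-1], 0), c(0, bmax[-length(bmax)]))
  thr <- 0.5 * bmax_sm[bid]
  above <- as.vector(energy > thr & energy > 1e-12)
  if (!any(above)) {
    return(new_r_peak_series(numeric(0), acceptable = FALSE))
  }
  # contiguous regions above threshold -> local signal maximum
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  regs <- which(r$values)
  peak_idx <- vapply(regs, function(j) {
    i0 <- starts[j]; i1 <- ends[j]
    i0 + which.max(x[i0:i1]) - 1L
  }, integer(1))
  # refractory: greedy keep-largest within refractory_s
  ord <- order(peak_idx)
  peak_idx <- peak_idx[ord]
  keep <- rep(TRUE, length(peak_idx))
  last <- 1L
  if (length(peak_idx) > 1L) {
    for (i in 2:length(peak_idx)) {
      if ((peak_idx[i] - peak_idx[last]) / fs < refractory_s) {
        if (x[peak_idx[i]] > x[peak_idx[last]]) {
          keep[last] <- FALSE; last <- i
        } else keep[i] <- FALSE
      } else last <- i
    }
  }
  peak_idx <- peak_idx[keep]
  times <- ch$time_s[peak_idx]
  amps <- x[peak_idx]
  # physiological gating: drop the smaller peak of any RR < 0.25 s
  repeat {
    rr <- diff(times)
    bad <- which(rr < 0.25)
    if (!length(bad)) break
    i <- bad[1]
    drop <- if (amps[i] < amps[i + 1]) i else i + 1L
    times <- times[-drop]; amps <- amps[-drop]
  }
  acceptable <- !(channel_duration(ch) >= 60 && length(times) < 10)
  new_r_peak_series(times, acceptable = acceptable)
}

#' Construct an R-peak series from known peak times
#'
#' Wraps a vector of R-peak times (seconds) in the container
#' [detect_r_peaks()] produces, e.g. for feeding simulator ground truth or
#' externally detected beats into [heart_rate_series()] and [lf_hf()].
#'
#' @param times Increasing numeric vector of peak times in seconds.
#' @param acceptable Whether the series passes the detection QC gate.
#' @return A tibble of class `r_peak_series`.
#' @export
r_peak_series <- function(times, acceptable = TRUE) {
  stopifnot(!is.unsorted(times))
  new_r_peak_series(times, acceptable = acceptable)
}

new_r_peak_series <- function(times, acceptable = TRUE) {
  out <- tibble::tibble(time_s = as.numeric(times))
  attr(out, "acceptable") <- acceptable
  class(out) <- c("r_peak_series", class(out))
  out
}

#' RR intervals of an R-peak series
#'
#' @param rp An `r_peak_series` from [detect_r_peaks()].
#' @return Tibble with `t_mid_s` (interval midpoint) and `rr_s`, restricted
#'   to physiologically plausible intervals (0.25-3 s).
#' @export
rr_intervals <- function(rp) {
  t <- rp$time_s
  if (length(t) < 2L) return(tibble::tibble(t_mid_s = numeric(), rr_s = numeric()))
  rr <- diff(t)
  mid <- (t[-1] + t[-length(t)]) / 2
  ok <- rr > 0.25 & rr < 3
  tibble::tibble(t_mid_s = mid[ok], rr_s = rr[ok])
}

#' Per-minute heart rate series
#'
#' Splits the session span into 1-minute windows (ten windows for the
#' standard 600 s experience) and computes, per window, HR = 60 / mean(RR)
#' over the RR intervals whose midpoint lies in the window. A final partial
#' window shorter than 30 s is dropped; windows with fewer than two usable
#' intervals are missing (`NA`).
#'
#' @param rp An `r_peak_series`.
#' @param span_s Session span in seconds (time is relative to
#'   experience start).
#' @param window_s Window length, 60 s by default.
#' @return Tibble with `window`, `t_start_s`, `t_end_s`, `hr_bpm`.
#' @export
heart_rate_series <- function(rp, span_s = 600, window_s = 60) {
  starts <- window_starts(span_s, window_s)
  ends <- pmin(starts + window_s, span_s)
  ok_win <- (ends - starts) >= window_s / 2
  starts <- starts[ok_win]; ends <- ends[ok_win]
  rr <- rr_intervals(rp)
  hr <- vapply(seq_along(starts), function(i) {
    sel <- rr$t_mid_s >= starts[i] & rr$t_mid_s < ends[i]
    if (sum(sel) < 2L) return(NA_real_)
    60 / mean(rr$rr_s[sel])
  }, numeric(1))
  tibble::tibble(window = seq_along(starts), t_start_s = starts,
                 t_end_s = ends, hr_bpm = hr)
}
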