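#' Respiration processing parameters
#'
#' Defaults implement the respiration pipeline: 0.1 Hz zero-phase high-pass
#' to remove drift, resampling to a fixed 100 Hz grid, sliding-window FFT
#' estimation of the breathing period (30 s windows, 15 s stride, searching
#' 0.05-1 Hz, i.e. 3-60 breaths/min), period-guided moving-average
#' smoothing (kernel = 0.25 period; the smoother must not erase the cycle it
#' measures), resampling back, and unit-SD normalization. Onsets are the
#' crossings between the smoothed signal and its moving mean (window = one
#' local period); breaths below the 0.25 amplitude threshold (in normalized
#' units) are discarded. Sessions whose mean breath rate reaches 20
#' breaths/min fail the quality gate.
#'
#' @param highpass_hz Drift-removal high-pass cutoff.
#' @param resample_hz Fixed processing rate.
#' @param est_window_s,est_stride_s Sliding-window geometry for period
#'   estimation.
#' @param period_band_hz Search band for the spectral peak.
#' @param smooth_kernel_periods Moving-average kernel as a fraction of the
#'   estimated period. A half-period kernel nulls all even harmonics of the
#'   cycle while keeping the fundamental (attenuated by sinc(1/2) = 0.64);
#'   slow paced breathing leaves the drift high-pass with its fundamental
#'   suppressed and its waveform bimodal, and a shorter kernel would retain
#'   that spurious second bump as a false breath.
#' @param moving_mean_periods Moving-mean window (for onset detection) in
#'   periods.
#' @param min_amplitude Minimum peak-to-trough breath amplitude, in units of
#'   the unit-SD normalized smoothed signal.
#' @param qa_max_bpm Sessions at or above this mean rate fail QA.
#' @param default_period_s Fallback period when the first window has a flat
#'   spectrum.
#' @return List of class `resp_params`.
#' @export
resp_params <- function(highpass_hz = 0.1, resample_hz = 100,
                        est_window_s = 45, est_stride_s = 15,
                        period_band_hz = c(0.05, 1),
                        smooth_kernel_periods = 0.5,
                        moving_mean_periods = 1,
                        min_amplitude = 0.25, qa_max_bpm = 20,
                        default_period_s = 4) {
  stopifnot(highpass_hz < resample_hz / 2, qa_max_bpm > 0,
            period_band_hz[1] < period_band_hz[2])
  structure(list(highpass_hz = highpass_hz, resample_hz = resample_hz,
                 est_window_s = est_window_s, est_stride_s = est_stride_s,
                 period_band_hz = period_band_hz,
                 smooth_kernel_periods = smooth_kernel_periods,
                 moving_mean_periods = moving_mean_periods,
                 min_amplitude = min_amplitude, qa_max_bpm = qa_max_bpm,
                 default_period_s = default_period_s),
            class = c("resp_params", "list"))
}

# Dominant period of a window by FFT magnitude peak within the search band:
# Hann-tapered, 4x zero-padded, refined by parabolic interpolation on the
# log magnitude. Breathing waveforms with holds (paced 4-7-8) carry strong
# harmonics, so the peak is checked against its subharmonics: if the
# magnitude at f/2 or f/3 reaches half the peak magnitude, the lower
# frequency (longer period) wins. Returns NA when the spectrum is flat in
# the band (no peak at least 3x the band median).
fft_period <- function(x, fs, band, gain = NULL) {
  n <- length(x)
  x <- x - mean(x)
  if (all(abs(x) < 1e-12)) return(NA_real_)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  nfft <- 4L * n
  mag <- Mod(stats::fft(c(x * w, rep(0, nfft - n))))[1:(nfft %/% 2 + 1L)]
  freq <- (0:(nfft %/% 2)) * fs / nfft
  if (!is.null(gain)) mag <- mag / pmax(gain(freq), 1e-3)
  sel <- which(freq >= band[1] & freq <= band[2])
  if (length(sel) < 3L) return(NA_real_)
  m <- mag[sel]
  if (max(m) < 3 * stats::median(m) || max(m) < 1e-10) return(NA_real_)
  i <- sel[which.max(m)]
  # local magnitude near a frequency: max within one unpadded bin
  local_mag <- function(f0) {
    j <- which(abs(freq - f0) <= fs / n / 2)
    if (!length(j)) 0 else max(mag[j])
  }
  fpeak <- freq[i]
  for (div in c(3, 2)) {
    fsub <- fpeak / div
    if (fsub >= band[1] && local_mag(fsub) >= 0.5 * mag[i]) {
      i <- which(abs(freq - fsub) <= fs / n / 2)
      i <- i[which.max(mag[i])]
      break
    }
  }
  # parabolic refinement on log magnitude (guard the array ends)
  if (i > 1L && i < length(mag)) {
    y1 <- log(mag[i - 1L] + 1e-300); y2 <- log(mag[i] + 1e-300)
    y3 <- log(mag[i + 1L] + 1e-300)
    denom <- y1 - 2 * y2 + y3
    delta <- if (abs(denom) > 1e-12) 0.5 * (y1 - y3) / denom else 0
    delta <- max(-0.5, min(0.5, delta))
  } else delta <- 0
  fpeak <- (i - 1 + delta) * fs / nfft
  if (fpeak <= 0) return(NA_real_)
  1 / fpeak
}

#' Smooth a respiration channel with windowed-FFT period guidance
#'
#' High-passes the channel, resamples it to the fixed processing rate,
#' estimates the breathing period per sliding window by FFT (falling back to
#' the previous window's period, or the default, when a window's spectrum is
#' flat), smooths with a moving average whose kernel follows the local
#' period estimate (each sample takes the minimum period over the windows
#' covering it, so a rate transition never erases the faster cycles),
#' resamples back to the original rate and normalizes the result to unit
#' standard deviation.
#'
#' @param ch A RESP [channel()] spanning at least one estimation window.
#' @param params A [resp_params()] list.
#' @return List of class `resp_smoothed` with `channel` (smoothed, unit-SD,
#'   at the original rate), `periods` (tibble: `window`, `t_center_s`,
#'   `period_s`, `fallback`), and `notes`.
#' @export
smooth_respiration <- function(ch, params = resp_params()) {
  stopifnot(is_channel(ch))
  fs0 <- channel_fs(ch)
  san <- sanitize_samples(ch$time_s, ch$value)
  if (diff(range(san$time_s)) < params$est_window_s) {
    stop("respiration channel shorter than one estimation window (",
         params$est_window_s, " s)")
  }
  x <- butter_filtfilt(san$value, fs0, params$highpass_hz, type = "high", order = 2)
  fs <- params$resample_hz
  tt <- seq(san$time_s[1], san$time_s[length(san$time_s)], by = 1 / fs)
  xr <- stats::approx(san$time_s, x, xout = tt, rule = 2, ties = "ordered")$y
  n <- length(xr)
  # a (near-)constant input leaves only the filter's numerical residue
  # after drift removal; treat every window as spectrally flat then
  scale <- max(stats::sd(san$value), mean(abs(san$value)))
  flat_input <- !is.finite(scale) || scale == 0 ||
    stats::sd(xr) < 1e-4 * scale
  wlen <- as.integer(round(params$est_window_s * fs))
  stride <- as.integer(round(params$est_stride_s * fs))
  starts <- seq(1L, max(1L, n - wlen + 1L), by = stride)
  notes <- character(0)

  periods <- numeric(length(starts)); fallback <- logical(length(starts))
  w_start <- numeric(length(starts)); w_end <- numeric(length(starts))
  prev_period <- NA_real_
  # the zero-phase order-2 high-pass scales amplitudes by 1/(1+(fc/f)^4);
  # the period estimator undoes that so slow paced breathing (whose
  # fundamental sits below the cutoff) is not mistaken for its harmonic
  hp_gain <- function(f) 1 / (1 + (params$highpass_hz / pmax(f, 1e-6))^4)
  for (j in seq_along(starts)) {
    i0 <- starts[j]
    i1 <- min(i0 + wlen - 1L, n)
    w_start[j] <- tt[i0]; w_end[j] <- tt[i1]
    p <- if (flat_input) NA_real_ else
      fft_period(xr[i0:i1], fs, params$period_band_hz, gain = hp_gain)
    fb <- is.na(p)
    if (fb) {
      p <- if (!is.na(prev_period)) prev_period else {
        notes <- c(notes, sprintf("window %d: flat spectrum, default period %g s used",
                                  j, params$default_period_s))
        params$default_period_s
      }
    }
    prev_period <- p
    periods[j] <- p; fallback[j] <- fb
  }
  # per-sample period from the window whose center is nearest: at a rate
  # transition the switch then falls halfway between the adjacent window
  # centers, i.e. at the transition itself, so neither regime is smoothed
  # with the other's kernel for long. Residual under-smoothing right at the
  # boundary is handled by the refractory merge in detect_breath_onsets().
  centers <- (w_start + w_end) / 2
  if (length(centers) > 1L) {
    cuts <- (centers[-1] + centers[-length(centers)]) / 2
    p_s <- periods[findInterval(tt, cuts) + 1L]
  } else {
    p_s <- rep(periods[1], n)
  }
  xs <- moving_average_variable(xr, params$smooth_kernel_periods * p_s * fs / 2)
  # back to the original sampling grid
  x0 <- stats::approx(tt, xs, xout = san$time_s, rule = 2, ties = "ordered")$y
  p0 <- stats::approx(tt, p_s, xout = san$time_s, rule = 2, ties = "ordered")$y
  s <- stats::sd(x0)
  if (!flat_input && is.finite(s) && s > 1e-12) x0 <- x0 / s else
    notes <- c(notes, "near-constant signal: unit-SD normalization skipped")
  structure(list(channel = rebuild_channel(ch, san$time_s, x0),
                 periods = tibble::tibble(window = seq_along(starts),
                                          t_start_s = w_start,
                                          t_end_s = w_end,
                                          t_center_s = (w_start + w_end) / 2,
                                          period_s = periods,
                                          fallback = fallback),
                 period_at = p0,
                 notes = notes),
            class = "resp_smoothed")
}

new_breath_events <- function(breaths, inhalation_onsets_s, exhalation_onsets_s,
                              crossings = NULL, notes = character(0)) {
  structure(list(breaths = tibble::as_tibble(breaths),
                 inhalation_onsets_s = inhalation_onsets_s,
                 exhalation_onsets_s = exhalation_onsets_s,
                 crossings = crossings,
                 notes = notes),
            class = "breath_events")
}

#' @export
print.breath_events <- function(x, ...) {
  cat(sprintf("<breath_events> %d breaths | %d inhalation / %d exhalation onsets\n",
              nrow(x$breaths), length(x$inhalation_onsets_s),
              length(x$exhalation_onsets_s)))
  invisible(x)
}

#' Detect breath onsets by moving-mean crossings
#'
#' Computes the moving mean of the smoothed, unit-SD respiration signal over
#' one local period (interpolated from the per-window period estimates) and
#' finds its crossings with the signal: upward crossings are inhalation
#' onsets, downward crossings exhalation onsets. Alternation is repaired by
#' dropping the earlier of two consecutive same-type onsets; breaths are
#' assembled as inhalation, exhalation, next inhalation, and any breath
#' whose peak-to-trough amplitude falls below the minimum amplitude is
#' deleted together with its onsets.
#'
#' Two robustness steps follow the crossing detection. Breaths whose
#' inhalation onsets lie closer than half the local period are merged
#' (keeping the earlier onset and the larger amplitude): very slow paced
#' breathing leaves the drift high-pass with most of its fundamental
#' removed, and residual harmonics can split one cycle into two crossings.
#' Finally, onset times are refined from the raw intercept to the adjacent
#' signal extremum (inhalation to the preceding trough, exhalation to the
#' intervening peak), since a mean crossing trails the turn of breath by up
#' to a quarter cycle; set `refine` to `FALSE` to keep the raw intercept
#' times (the `crossings` element always retains them).
#'
#' @param smoothed A `resp_smoothed` object from [smooth_respiration()].
#' @param params A [resp_params()] list.
#' @param refine Refine onset times from mean crossings to the adjacent
#'   extrema (default `TRUE`).
#' @return A `breath_events` object: `breaths` tibble (`inh_s`, `exh_s`,
#'   `amplitude`), the retained onset vectors, and `crossings` (all raw
#'   signal/moving-mean intercepts with their slope classification).
#' @export
detect_breath_onsets <- function(smoothed, params = resp_params(), refine = TRUE) {
  stopifnot(inherits(smoothed, "resp_smoothed"))
  ch <- smoothed$channel
  fs <- channel_fs(ch)
  x <- ch$value
  t <- ch$time_s
  per <- smoothed$period_at
  mm <- moving_average_variable(x, params$moving_mean_periods * per * fs / 2)
  d <- x - mm
  s <- sign(d)
  # carry the previous sign through exact zeros
  for (i in which(s == 0)) s[i] <- if (i > 1) s[i - 1] else 1
  chg <- which(diff(s) != 0)
  if (!length(chg)) {
    return(new_breath_events(tibble::tibble(inh_s = numeric(), exh_s = numeric(),
                                            amplitude = numeric()),
                             numeric(0), numeric(0),
                             notes = "no mean crossings found"))
  }
  # linear interpolation of the crossing time
  tc <- t[chg] + (t[chg + 1L] - t[chg]) * (0 - d[chg]) / (d[chg + 1L] - d[chg])
  type <- ifelse(s[chg + 1L] > 0, "inhalation", "exhalation")
  # alternation repair: drop the earlier of two same-type consecutive onsets
  keep <- rep(TRUE, length(tc))
  for (i in seq_len(length(tc) - 1L)) {
    if (type[i] == type[i + 1L]) keep[i] <- FALSE
  }
  tc <- tc[keep]; type <- type[keep]
  crossings <- tibble::tibble(time_s = tc, type = type)
  inh <- tc[type == "inhalation"]
  exh <- tc[type == "exhalation"]
  # assemble breaths: inhalation -> exhalation -> next inhalation
  breaths <- list()
  for (i in seq_along(inh)) {
    e <- exh[exh > inh[i]]
    if (!length(e)) next
    e <- e[1]
    next_i <- inh[inh > inh[i]]
    end_t <- if (length(next_i)) next_i[1] else t[length(t)]
    if (e >= end_t && length(next_i)) next  # no exhalation inside this breath
    peak <- max(x[t >= inh[i] & t <= e])
    trough <- min(x[t >= e & t <= end_t])
    breaths[[length(breaths) + 1L]] <-
      tibble::tibble(inh_s = inh[i], exh_s = e, amplitude = peak - trough)
  }
  breaths <- if (length(breaths)) dplyr::bind_rows(breaths) else
    tibble::tibble(inh_s = numeric(), exh_s = numeric(), amplitude = numeric())
  local_period <- function(tt) interp_lin(t, per, tt)
  breaths <- breaths[breaths$amplitude >= params$min_amplitude, ]
  # a mean-crossing wiggle lasting a tiny fraction of the cycle is not an
  # inhale phase; its amplitude can look large only because the genuine
  # trough of the surrounding cycle is attributed to it
  if (nrow(breaths)) {
    breaths <- breaths[(breaths$exh_s - breaths$inh_s) >=
                         0.1 * local_period(breaths$inh_s), ]
  }
  # refractory merge: two inhalations within half a local period are one
  # cycle split by residual harmonics
  while (nrow(breaths) > 1L) {
    gaps <- diff(breaths$inh_s)
    # threshold on the smaller of the two local periods, so a genuine fast
    # breath just before a slow regime is never swallowed by it
    thr <- 0.5 * pmin(local_period(breaths$inh_s[-nrow(breaths)]),
                      local_period(breaths$inh_s[-1]))
    short <- which(gaps < thr)
    if (!length(short)) break
    i <- short[1]
    a <- breaths[i, ]; b <- breaths[i + 1L, ]
    keep_b <- b$amplitude > a$amplitude
    merged <- tibble::tibble(inh_s = a$inh_s,
                             exh_s = if (keep_b) b$exh_s else a$exh_s,
                             amplitude = max(a$amplitude, b$amplitude))
    breaths <- dplyr::bind_rows(breaths[seq_len(i - 1L), ], merged,
                                breaths[-seq_len(i + 1L), ])
  }
  # end-of-record completion: a trailing inhalation whose peak (the
  # exhalation onset) is reached before the record ends is a complete
  # breath even though its downward mean-crossing lies beyond the end —
  # the crossing trails the peak by up to a quarter cycle, the peak of the
  # zero-phase smoothed signal does not.
  if (length(inh)) {
    li <- inh[length(inh)]
    if (!any(exh > li)) {
      sel <- which(t >= li)
      spaced <- nrow(breaths) == 0L ||
        li - breaths$inh_s[nrow(breaths)] >= 0.5 * local_period(li)
      if (length(sel) > 3L && spaced) {
        pk <- which.max(x[sel])
        done <- pk > 1L && pk < length(sel)
        if (!done) {
          # the shrinking edge window of the smoother can push the peak
          # onto the boundary; if the upstroke has decayed the breath
          # turned within the record
          dx <- diff(x[sel])
          done <- max(dx) > 0 &&
            mean(utils::tail(dx, 3L)) < 0.25 * max(dx)
        }
        if (done) {
          amp <- x[sel[pk]] - min(x[sel])
          if (amp >= params$min_amplitude) {
            breaths <- dplyr::bind_rows(breaths, tibble::tibble(
              inh_s = li, exh_s = t[sel[pk]], amplitude = amp))
          }
        }
      }
    }
  }
  if (refine && nrow(breaths)) {
    for (i in seq_len(nrow(breaths))) {
      p <- local_period(breaths$inh_s[i])
      lo <- max(breaths$inh_s[i] - 0.75 * p,
                if (i > 1L) breaths$exh_s[i - 1L] else t[1], t[1])
      sel <- which(t >= lo & t <= breaths$inh_s[i])
      if (length(sel)) breaths$inh_s[i] <- t[sel[which.min(x[sel])]]
      sel <- which(t >= breaths$inh_s[i] & t <= breaths$exh_s[i])
      if (length(sel)) breaths$exh_s[i] <- t[sel[which.max(x[sel])]]
    }
  }
  new_breath_events(breaths, breaths$inh_s, breaths$exh_s, crossings = crossings)
}

#' Windowed breath rates, 5-minute counts and the rate QA gate
#'
#' Counts each breath in the 2-minute window containing its inhalation
#' onset (rate = count / 2 breaths per minute per window), reports the
#' breath counts over the first and last 5 minutes, and applies the quality
#' gate: the session fails when its overall mean rate is at or above the
#' maximum (20 breaths/min by default).
#'
#' @param ev A `breath_events` object (from [detect_breath_onsets()] or
#'   [ground_truth_breath_events()]).
#' @param params A [resp_params()] list.
#' @param span_s Session span in seconds.
#' @param window_s Rate window length (120 s).
#' @return List of class `breath_rates` with `rates` (tibble: `window`,
#'   `t_start_s`, `t_end_s`, `rate_bpm`), `count_first5`, `count_last5`,
#'   `mean_rate_bpm`, and `qa_pass`.
#' @export
breath_rate_series <- function(ev, params = resp_params(), span_s = 600,
                               window_s = 120) {
  stopifnot(inherits(ev, "breath_events"))
  onsets <- ev$breaths$inh_s
  starts <- window_starts(span_s, window_s)
  ends <- pmin(starts + window_s, span_s)
  counts <- vapply(seq_along(starts), function(i)
    sum(onsets >= starts[i] & onsets < ends[i]), numeric(1))
  rates <- counts / ((ends - starts) / 60)
  mean_rate <- length(onsets) / (span_s / 60)
  structure(
    list(rates = tibble::tibble(window = seq_along(starts), t_start_s = starts,
                                t_end_s = ends, rate_bpm = rates),
         count_first5 = sum(onsets >= 0 & onsets < min(300, span_s)),
         count_last5 = sum(onsets >= max(0, span_s - 300) & onsets < span_s),
         mean_rate_bpm = mean_rate,
         qa_pass = mean_rate < params$qa_max_bpm),
    class = "breath_rates"
  )
}
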