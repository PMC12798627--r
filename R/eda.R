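#' EDA processing parameters
#'
#' Defaults implement the electrodermal cleaning and quality rules: an
#' 8-second median filter, a 5 Hz zero-phase low-pass, linear interpolation
#' across EMG-flagged motion-artifact windows, a 0-100 quality index built
#' from the physiologically valid range (0.05-60 microsiemens) and a
#' maximum rate of change of 10 microsiemens per second evaluated on a
#' 1-second neighborhood, with rejection below a quality index of 50. The
#' motion-artifact detector runs the Local Outlier Factor over sliding EMG
#' windows; its window length, stride, neighbor count and flagging fraction
#' are tunable here (the method only requires "a high proportion of
#' outliers").
#'
#' @param median_kernel_s Median filter kernel length in seconds.
#' @param lowpass_hz Low-pass cutoff for high-frequency noise.
#' @param valid_range_uS Two-element physiological range in microsiemens.
#' @param max_rate_uS_per_s Maximum tolerated rate of change.
#' @param rate_window_s Neighborhood (one-sided) over which the rate is
#'   evaluated.
#' @param qi_reject_below Quality-index rejection threshold.
#' @param tonic_lowpass_hz Cutoff separating the tonic component.
#' @param lof_window_s,lof_stride_s Sliding-window geometry for the EMG
#'   outlier scan (a 5 s burst is covered by at least two windows).
#' @param lof_neighbors Number of neighbors for the Local Outlier Factor.
#' @param lof_threshold LOF score above which a sample is an outlier.
#' @param outlier_fraction_flag Window flagged when its outlier fraction
#'   exceeds this.
#' @param max_artifact_coverage Channel unacceptable when flagged windows
#'   cover more than this fraction of it.
#' @return List of class `eda_params`.
#' @export
eda_params <- function(median_kernel_s = 8, lowpass_hz = 5,
                       valid_range_uS = c(0.05, 60), max_rate_uS_per_s = 10,
                       rate_window_s = 1, qi_reject_below = 50,
                       tonic_lowpass_hz = 0.05,
                       lof_window_s = 4, lof_stride_s = 2, lof_neighbors = 20,
                       lof_threshold = 1.5, outlier_fraction_flag = 0.10,
                       max_artifact_coverage = 0.5) {
  stopifnot(valid_range_uS[1] < valid_range_uS[2],
            qi_reject_below >= 0, qi_reject_below <= 100, lowpass_hz > 0)
  structure(list(median_kernel_s = median_kernel_s, lowpass_hz = lowpass_hz,
                 valid_range_uS = valid_range_uS,
                 max_rate_uS_per_s = max_rate_uS_per_s,
                 rate_window_s = rate_window_s,
                 qi_reject_below = qi_reject_below,
                 tonic_lowpass_hz = tonic_lowpass_hz,
                 lof_window_s = lof_window_s, lof_stride_s = lof_stride_s,
                 lof_neighbors = lof_neighbors, lof_threshold = lof_threshold,
                 outlier_fraction_flag = outlier_fraction_flag,
                 max_artifact_coverage = max_artifact_coverage),
            class = c("eda_params", "list"))
}

# Exact Local Outlier Factor. `lof_reference()` precomputes, for a reference
# point set, each reference point's k-distance and local reachability
# density; `lof_scores()` then scores query points against that reference
# (k nearest reference neighbors, LOF = mean neighbor density / own
# density). Scoring against a fixed global reference keeps the factor
# sensitive to sustained amplitude bursts: a plain within-window LOF is
# scale-free, so a window lying entirely inside a burst would look exactly
# like a quiet window.
lof_reference <- function(ref, k) {
  n <- nrow(ref)
  k <- max(1L, min(k, n - 1L))
  dm <- as.matrix(stats::dist(ref))
  diag(dm) <- Inf
  nn_idx <- matrix(0L, n, k)
  kdist <- numeric(n)
  for (i in seq_len(n)) {
    ord <- order(dm[i, ])
    nn_idx[i, ] <- ord[seq_len(k)]
    kdist[i] <- dm[i, nn_idx[i, k]]
  }
  lrd <- numeric(n)
  for (i in seq_len(n)) {
    nb <- nn_idx[i, ]
    reach <- pmax(kdist[nb], dm[i, nb])
    lrd[i] <- 1 / pmax(mean(reach), 1e-12)
  }
  list(pts = ref, k = k, kdist = kdist, lrd = lrd)
}

lof_scores <- function(query, ref_model, chunk = 4000L) {
  k <- ref_model$k
  ref <- ref_model$pts
  tref <- t(ref)
  rf2 <- colSums(tref^2)
  nq <- nrow(query)
  lof <- numeric(nq)
  for (c0 in seq(1L, nq, by = chunk)) {
    rows <- c0:min(c0 + chunk - 1L, nq)
    q <- query[rows, , drop = FALSE]
    d2 <- outer(rowSums(q^2), rf2, "+") - 2 * q %*% tref
    d2[d2 < 0] <- 0
    dmn <- -sqrt(d2)
    m <- length(rows)
    # k passes of row-minima instead of a per-row sort
    nn_val <- matrix(0, m, k)
    nn_idx <- matrix(0L, m, k)
    ii <- seq_len(m)
    for (s in seq_len(k)) {
      j <- max.col(dmn, ties.method = "first")
      cells <- cbind(ii, j)
      nn_idx[, s] <- j
      nn_val[, s] <- -dmn[cells]
      dmn[cells] <- -Inf
    }
    reach <- pmax(matrix(ref_model$kdist[nn_idx], m, k), nn_val)
    lrd_q <- 1 / pmax(rowMeans(reach), 1e-12)
    lof[rows] <- rowMeans(matrix(ref_model$lrd[nn_idx], m, k)) / lrd_q
  }
  lof[!is.finite(lof)] <- 1
  lof
}

#' Detect motion-artifact windows from EMG
#'
#' The EMG signal is z-score normalized over the whole segment and scanned
#' with sliding windows; within each window the Local Outlier Factor of
#' every sample is computed over 2-D points (sample value, first
#' difference) — raw scalar LOF is insensitive to fast transients of equal
#' amplitude. Outlierness is scored against a fixed, evenly-spaced
#' reference sample of the whole normalized recording, so a burst that
#' fills an entire window is still outlying (the factor is otherwise
#' scale-free). A window is flagged when the fraction of LOF outliers
#' exceeds the configured proportion; flagged windows are merged into
#' disjoint intervals.
#'
#' @param emg An EMG [channel()], or `NULL` when the modality is absent (an
#'   empty result with a QC note is returned and the EDA proceeds
#'   uninterpolated).
#' @param params An [eda_params()] list.
#' @return List of class `artifact_windows` with `intervals` (tibble
#'   `start_s`, `end_s`), `window_info` (per scanned window: start, end,
#'   outlier fraction, flagged), and `note`.
#' @export
detect_motion_windows <- function(emg, params = eda_params()) {
  if (is.null(emg)) {
    return(structure(list(intervals = tibble::tibble(start_s = numeric(), end_s = numeric()),
                          window_info = NULL, note = "EMG absent; no artifact detection"),
                     class = "artifact_windows"))
  }
  stopifnot(is_channel(emg))
  fs <- channel_fs(emg)
  san <- sanitize_samples(emg$time_s, emg$value)
  x <- san$value
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    return(structure(list(intervals = tibble::tibble(start_s = numeric(), end_s = numeric()),
                          window_info = NULL, note = "constant EMG; no outliers definable"),
                     class = "artifact_windows"))
  }
  z <- (x - mean(x)) / s
  pts_all <- cbind(z, c(0, diff(z)))
  n <- length(z)
  ref_n <- min(400L, n)
  ref <- lof_reference(pts_all[unique(round(seq(1L, n, length.out = ref_n))), ,
                               drop = FALSE],
                       params$lof_neighbors)
  # each sample's outlierness is scored once against the global reference;
  # sliding windows then just aggregate the labels
  outlier <- lof_scores(pts_all, ref) > params$lof_threshold
  wlen <- max(2L, as.integer(round(params$lof_window_s * fs)))
  stride <- max(1L, as.integer(round(params$lof_stride_s * fs)))
  if (wlen >= n) {
    starts_i <- 1L
    wlen <- n
  } else {
    starts_i <- seq(1L, n - wlen + 1L, by = stride)
  }
  cs <- cumsum(c(0, outlier))
  ends_i <- pmin(starts_i + wlen - 1L, n)
  frac <- (cs[ends_i + 1L] - cs[starts_i]) / (ends_i - starts_i + 1L)
  info <- tibble::tibble(start_s = san$time_s[starts_i],
                         end_s = san$time_s[ends_i],
                         outlier_fraction = frac,
                         flagged = frac > params$outlier_fraction_flag)
  intervals <- merge_intervals(info[info$flagged, c("start_s", "end_s")])
  structure(list(intervals = intervals, window_info = info, note = NULL),
            class = "artifact_windows")
}

#' Clean an EDA channel
#'
#' Applies the 8 s median filter, then the 5 Hz zero-phase low-pass (skipped
#' with a note when the sampling rate cannot support it), then replaces
#' samples inside motion-artifact windows by linear interpolation between
#' the nearest clean boundary samples; windows touching the channel edge are
#' filled by nearest-clean-value extension.
#'
#' @param eda An EDA [channel()].
#' @param windows An `artifact_windows` object from [detect_motion_windows()]
#'   (or `NULL` for none).
#' @param params An [eda_params()] list.
#' @return List of class `eda_clean` with `channel`, `artifact_coverage`
#'   (fraction of samples interpolated), `acceptable` (`FALSE` when coverage
#'   exceeds half the channel), and `notes`.
#' @export
clean_eda <- function(eda, windows = NULL, params = eda_params()) {
  stopifnot(is_channel(eda))
  fs <- channel_fs(eda)
  san <- sanitize_samples(eda$time_s, eda$value)
  x <- san$value
  k <- as.integer(round(params$median_kernel_s * fs))
  if (k %% 2L == 0L) k <- k + 1L
  if (k >= 3L && k < length(x)) x <- stats::runmed(x, k, endrule = "median")
  notes <- character(0)
  if (fs > 2 * params$lowpass_hz) {
    x <- butter_filtfilt(x, fs, params$lowpass_hz, type = "low", order = 4)
  } else {
    notes <- c(notes, sprintf("low-pass at %g Hz skipped: fs = %g Hz too low",
                              params$lowpass_hz, fs))
  }
  intervals <- if (inherits(windows, "artifact_windows")) windows$intervals else
    merge_intervals(windows)
  inside <- in_any_interval(san$time_s, intervals)
  coverage <- mean(inside)
  if (any(inside) && !all(inside)) {
    x[inside] <- stats::approx(san$time_s[!inside], x[!inside],
                               xout = san$time_s[inside], rule = 2,
                               ties = "ordered")$y
  }
  structure(list(channel = rebuild_channel(eda, san$time_s, x),
                 artifact_coverage = coverage,
                 acceptable = coverage <= params$max_artifact_coverage,
                 notes = notes),
            class = "eda_clean")
}

#' EDA quality index
#'
#' A sample violates quality when it lies outside the physiological range
#' (0.05-60 microsiemens) or when the absolute change between it and any
#' sample within one second exceeds 10 microsiemens per second of lag. The
#' quality index is 100 times the non-violating fraction; the channel is
#' unacceptable when the index falls below 50.
#'
#' @param eda A cleaned EDA [channel()].
#' @param params An [eda_params()] list.
#' @return List with `qi` (0-100), `acceptable`, and the two violating
#'   fractions (`frac_range`, `frac_rate`).
#' @export
eda_quality_index <- function(eda, params = eda_params()) {
  stopifnot(is_channel(eda))
  if (nrow(eda) == 0L) stop("empty EDA channel")
  x <- eda$value
  n <- length(x)
  fs <- channel_fs(eda)
  out_of_range <- x < params$valid_range_uS[1] | x > params$valid_range_uS[2]
  rate_viol <- rep(FALSE, n)
  max_lag <- max(1L, as.integer(floor(params$rate_window_s * fs)))
  for (lag in seq_len(max_lag)) {
    dt <- lag / fs
    d <- abs(x[(1 + lag):n] - x[1:(n - lag)]) / dt
    hit <- d > params$max_rate_uS_per_s
    if (any(hit)) {
      rate_viol[which(hit)] <- TRUE
      rate_viol[which(hit) + lag] <- TRUE
    }
  }
  violating <- out_of_range | rate_viol
  qi <- 100 * (1 - mean(violating))
  list(qi = qi, acceptable = qi >= params$qi_reject_below,
       frac_range = mean(out_of_range), frac_rate = mean(rate_viol))
}

#' Tonic EDA series over 2-minute windows
#'
#' Extracts the tonic (slow-varying) component with a zero-phase low-pass at
#' the configured tonic cutoff and averages it over non-overlapping 2-minute
#' windows relative to experience start. A final partial window shorter than
#' 60 s is dropped.
#'
#' @param eda A cleaned, accepted EDA [channel()].
#' @param params An [eda_params()] list.
#' @param span_s Session span in seconds.
#' @param window_s Window length (120 s).
#' @return Tibble with `window`, `t_start_s`, `t_end_s`, `tonic_uS`.
#' @export
tonic_series <- function(eda, params = eda_params(), span_s = 600, window_s = 120) {
  stopifnot(is_channel(eda))
  fs <- channel_fs(eda)
  x <- eda$value
  if (fs > 2 * params$tonic_lowpass_hz * 10) {
    x <- butter_filtfilt(x, fs, params$tonic_lowpass_hz, type = "low", order = 2)
  }
  starts <- window_starts(span_s, window_s)
  ends <- pmin(starts + window_s, span_s)
  ok_win <- (ends - starts) >= window_s / 2
  starts <- starts[ok_win]; ends <- ends[ok_win]
  tonic <- vapply(seq_along(starts), function(i) {
    sel <- eda$time_s >= starts[i] & eda$time_s < ends[i]
    if (!any(sel)) return(NA_real_)
    mean(x[sel])
  }, numeric(1))
  tibble::tibble(window = seq_along(starts), t_start_s = starts,
                 t_end_s = ends, tonic_uS = tonic)
}
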