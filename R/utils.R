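# Internal numerical helpers shared across modules.

#' @importFrom stats approx fft pchisq pnorm pt qnorm rnorm runif rexp sd var
#' @importFrom utils head tail
NULL

# Forward-backward (zero-phase) IIR filtering with odd-reflection padding at
# both ends, so low-cutoff filters do not ring at the signal edges.
filtfilt_padded <- function(b, a, x, padlen) {
  n <- length(x)
  padlen <- max(0L, min(as.integer(padlen), n - 1L))
  if (padlen > 0L) {
    pre <- 2 * x[1] - x[(padlen + 1L):2L]
    post <- 2 * x[n] - x[(n - 1L):(n - padlen)]
    xp <- c(pre, x, post)
  } else xp <- x
  y <- as.numeric(signal::filtfilt(b, a, xp))
  if (padlen > 0L) y[(padlen + 1L):(padlen + n)] else y
}

# Zero-phase Butterworth filtering. `cutoff` in Hz (length 1 or 2);
# signal::filtfilt doubles the effective order, so `order` is the designed
# prototype order. Padding scales with the lowest corner frequency.
butter_filtfilt <- function(x, fs, cutoff, type = c("low", "high", "pass"), order = 4) {
  type <- match.arg(type)
  w <- cutoff / (fs / 2)
  if (any(w <= 0) || any(w >= 1)) {
    stop("filter cutoff must lie strictly inside (0, fs/2); got ",
         paste(cutoff, collapse = ", "), " Hz at fs = ", fs, " Hz")
  }
  bf <- signal::butter(order, w, type = type)
  padlen <- max(50, ceiling(2 * fs / min(cutoff)))
  filtfilt_padded(bf$b, bf$a, x, padlen)
}

# Second-order IIR notch (biquad), applied forward-backward for zero phase.
notch_filtfilt <- function(x, fs, freq, q = 30) {
  if (freq >= fs / 2) return(x)  # powerline above Nyquist: nothing to remove
  w0 <- 2 * pi * freq / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  b <- b / a[1]
  a <- a / a[1]
  filtfilt_padded(b, a, x, max(50, ceiling(3 * fs * q / freq / (2 * pi))))
}

# Centered moving average with shrinking (partial) windows at the edges.
# `k` is the full window length in samples.
moving_average <- function(x, k) {
  n <- length(x)
  k <- max(1L, as.integer(round(k)))
  if (k <= 1L || n == 0L) return(x)
  h <- k %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Centered moving average with a per-sample half-width (samples).
moving_average_variable <- function(x, half_width) {
  n <- length(x)
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  h <- pmax(1L, as.integer(round(half_width)))
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Start times of consecutive analysis windows covering [0, span_s).
window_starts <- function(span_s, window_s) {
  n <- ceiling(span_s / window_s - 1e-9)
  window_s * (seq_len(max(n, 0L)) - 1)
}

# Trapezoidal integral of y over x.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

# Linear interpolation with constant extrapolation at the ends.
interp_lin <- function(x, y, xout) {
  if (length(x) == 1L) return(rep(y, length(xout)))
  stats::approx(x, y, xout = xout, rule = 2, ties = "ordered")$y
}

# Replace non-finite interior values by linear interpolation; drop
# leading/trailing non-finite samples. Returns index range kept + values.
sanitize_samples <- function(time_s, value) {
  ok <- is.finite(value)
  if (!any(ok)) stop("channel has no finite samples")
  first <- which(ok)[1]
  last <- tail(which(ok), 1)
  keep <- first:last
  t <- time_s[keep]
  v <- value[keep]
  bad <- !is.finite(v)
  if (any(bad)) v[bad] <- stats::approx(t[!bad], v[!bad], xout = t[bad], ties = "ordered")$y
  list(time_s = t, value = v, n_interpolated = sum(bad), n_dropped = length(value) - length(keep))
}

# Merge overlapping/adjacent intervals given as a data frame with
# start_s/end_s columns; returns them sorted and disjoint.
merge_intervals <- function(intervals) {
  if (is.null(intervals) || nrow(intervals) == 0L) {
    return(tibble::tibble(start_s = numeric(), end_s = numeric()))
  }
  iv <- intervals[order(intervals$start_s), c("start_s", "end_s")]
  out_s <- iv$start_s[1]
  out_e <- iv$end_s[1]
  if (nrow(iv) > 1L) {
    for (i in 2:nrow(iv)) {
      if (iv$start_s[i] <= tail(out_e, 1)) {
        out_e[length(out_e)] <- max(tail(out_e, 1), iv$end_s[i])
      } else {
        out_s <- c(out_s, iv$start_s[i])
        out_e <- c(out_e, iv$end_s[i])
      }
    }
  }
  tibble::tibble(start_s = out_s, end_s = out_e)
}

# Logical: which times fall inside any of the (already merged) intervals.
in_any_interval <- function(t, intervals) {
  inside <- rep(FALSE, length(t))
  if (is.null(intervals) || nrow(intervals) == 0L) return(inside)
  for (i in seq_len(nrow(intervals))) {
    inside <- inside | (t >= intervals$start_s[i] & t <= intervals$end_s[i])
  }
  inside
}

# Evaluate an expression with a locally-set RNG seed, restoring the
# caller's RNG state afterwards (keeps sub-simulators independent).
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}
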