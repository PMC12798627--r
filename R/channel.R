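#' Construct a physiological channel
#'
#' A channel is a tibble with columns `time_s` and `value` plus attributes
#' describing the stream: `modality` (one of `"ECG"`, `"EDA"`, `"EMG"`,
#' `"RESP"`), the nominal sampling rate `fs` (Hz) and the device `units`
#' (mV for ECG/EMG, microsiemens for EDA, arbitrary units for respiration
#' impedance). Timestamps must be strictly increasing and are interpreted in
#' seconds relative to the recording start.
#'
#' @param time_s Numeric vector of sample times in seconds, strictly
#'   increasing.
#' @param value Numeric vector of samples in device units, same length as
#'   `time_s`.
#' @param modality Channel modality label, e.g. `"ECG"`.
#' @param fs Nominal sampling rate in Hz (> 0). Timestamps are authoritative;
#'   `fs` is used where a uniform grid is assumed (filtering, resampling).
#' @param units Unit string, for reporting only.
#'
#' @return A tibble of class `physio_channel`.
#' @examples
#' ch <- channel(seq(0, 1, by = 0.25), c(0, 1, 0, -1, 0), "RESP", fs = 4)
#' channel_fs(ch)
#' @export
channel <- function(time_s, value, modality, fs, units = "") {
  stopifnot(length(time_s) == length(value), length(time_s) >= 2, fs > 0)
  if (any(diff(time_s) <= 0)) stop("channel timestamps must be strictly increasing")
  out <- tibble::tibble(time_s = as.numeric(time_s), value = as.numeric(value))
  attr(out, "modality") <- toupper(modality)
  attr(out, "fs") <- as.numeric(fs)
  attr(out, "units") <- units
  class(out) <- c("physio_channel", class(out))
  out
}

# Rebuild a channel from an existing one with new samples, keeping metadata.
rebuild_channel <- function(ch, time_s, value) {
  channel(time_s, value, channel_modality(ch), channel_fs(ch), channel_units(ch))
}

#' @rdname channel
#' @param x Object to test or query.
#' @export
is_channel <- function(x) inherits(x, "physio_channel")

#' @rdname channel
#' @export
channel_fs <- function(x) attr(x, "fs")

#' @rdname channel
#' @export
channel_modality <- function(x) attr(x, "modality")

#' @rdname channel
#' @export
channel_units <- function(x) attr(x, "units")

#' @rdname channel
#' @export
channel_duration <- function(x) diff(range(x$time_s))

#' @export
print.physio_channel <- function(x, ...) {
  cat(sprintf("<physio_channel> %s | fs = %g Hz | %d samples | %.1f s | units: %s\n",
              channel_modality(x), channel_fs(x), nrow(x), channel_duration(x),
              channel_units(x)))
  NextMethod()
}

#' Construct a session recording
#'
#' One participant's multimodal recording: a named set of channels, the
#' experiment markers, and the group assignment (technology and stimulus
#' arms).
#'
#' @param participant_id Participant identifier string.
#' @param channels Named list of [channel()] objects keyed by modality
#'   (`ECG`, `EDA`, `EMG`, `RESP`); modalities may be absent.
#' @param markers Tibble with columns `label`, `time_s`; must eventually
#'   contain `experience_start` and `experience_end` for trimming.
#' @param tech,stim Between-subject group labels (`"MindGym"`/`"VR"` and
#'   `"Breathwork"`/`"Rain"`), or `NA` when unknown.
#'
#' @return A list of class `physio_session`.
#' @export
session_recording <- function(participant_id, channels, markers, tech = NA_character_,
                              stim = NA_character_) {
  stopifnot(is.list(channels))
  nm <- toupper(names(channels))
  if (anyDuplicated(nm)) stop("channel modality labels must be unique")
  names(channels) <- nm
  for (ch in channels) stopifnot(is_channel(ch))
  markers <- tibble::as_tibble(markers)
  stopifnot(all(c("label", "time_s") %in% names(markers)))
  structure(
    list(participant_id = participant_id, channels = channels,
         markers = markers, tech = tech, stim = stim),
    class = "physio_session"
  )
}

#' @export
print.physio_session <- function(x, ...) {
  cat(sprintf("<physio_session> %s | tech = %s | stim = %s\n",
              x$participant_id, x$tech, x$stim))
  cat("  channels:", if (length(x$channels)) paste(names(x$channels), collapse = ", ") else "(none)", "\n")
  cat("  markers: ", paste(sprintf("%s@%.1fs", x$markers$label, x$markers$time_s), collapse = ", "), "\n")
  invisible(x)
}

marker_time <- function(rec, label) {
  hit <- rec$markers$time_s[rec$markers$label == label]
  if (length(hit) == 0L) stop("marker '", label, "' not found in session ", rec$participant_id)
  hit[1]
}

#' Trim a session to the experiential window
#'
#' Restricts every channel to samples between the `experience_start` and
#' `experience_end` markers and rebases all times so that
#' `experience_start` becomes t = 0. All downstream windowing (2-minute
#' tonic means, per-minute heart rate, first/last 5 minutes) is computed on
#' this rebased clock. The operation is idempotent and never extends a
#' channel; a channel that falls entirely outside the marker window is
#' dropped (recorded as absent).
#'
#' @param rec A [session_recording()].
#' @param start_label,end_label Marker labels delimiting the experience.
#' @return A trimmed `physio_session`.
#' @export
trim_to_experience <- function(rec, start_label = "experience_start",
                               end_label = "experience_end") {
  t0 <- marker_time(rec, start_label)
  t1 <- marker_time(rec, end_label)
  if (t1 <= t0) stop("experience_end must be after experience_start")
  trimmed <- list()
  for (m in names(rec$channels)) {
    ch <- rec$channels[[m]]
    keep <- ch$time_s >= t0 & ch$time_s <= t1
    if (sum(keep) < 2L) next  # entirely (or all but one sample) outside: absent
    trimmed[[m]] <- rebuild_channel(ch, ch$time_s[keep] - t0, ch$value[keep])
  }
  markers <- rec$markers
  markers$time_s <- markers$time_s - t0
  session_recording(rec$participant_id, trimmed, markers, rec$tech, rec$stim)
}
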