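#' Simulation configuration for synthetic multimodal sessions
#'
#' Describes one synthetic 10-minute session with known ground truth. The
#' defaults emulate the study conditions the pipeline targets: a 600 s
#' experiential phase under either guided 4-7-8 breathwork (inhale 4 s /
#' hold 7 s / exhale 8 s, one cycle every 19 s after a 60 s free-breathing
#' lead-in) or free breathing at a constant base rate (the "rain" control),
#' heart rate with configurable spectral RR modulation in the LF/HF bands, a
#' slowly drifting tonic skin-conductance level with Poisson-timed phasic
#' responses, and EMG whose bursts mark motion-artifact windows that also
#' contaminate the EDA.
#'
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   output.
#' @param duration_s Session length in seconds (default 600).
#' @param protocol `"free_breathing"` or `"breathwork_478"`.
#' @param base_breath_rate_bpm Free-breathing rate in breaths/min (also the
#'   lead-in rate for breathwork).
#' @param breath_rate_trajectory Optional tibble (`time_s`, `bpm`) giving a
#'   piecewise-linear free-breathing rate trajectory; overrides
#'   `base_breath_rate_bpm` when supplied.
#' @param cycle_jitter_sd SD of the multiplicative lognormal jitter applied
#'   to each breath-cycle duration. Real breathing is not metronomic; this
#'   also gives breath counts realistic within-subject variability.
#' @param breathwork_leadin_s Free-breathing lead-in before pacing starts
#'   (breathwork protocol only).
#' @param mean_hr_bpm Mean heart rate in beats/min.
#' @param rr_modulation Tibble (`freq_hz`, `amplitude_s`) of sinusoidal RR
#'   modulation components (e.g. 0.1 Hz for LF, 0.3 Hz for HF).
#' @param rr_noise_sd_s SD of white noise added to each RR interval (s).
#' @param eda_tonic_trajectory Tibble (`time_s`, `uS`) piecewise-linear tonic
#'   skin conductance level.
#' @param scr_rate_per_min Poisson rate of phasic skin conductance responses.
#' @param scr_amplitude_uS SCR peak amplitude (1 s rise, exponential decay).
#' @param artifact_windows Tibble (`start_s`, `duration_s`, `gain`): motion
#'   bursts that multiply EMG amplitude by `gain` and add spiky
#'   contamination to the EDA. Overlapping windows are merged.
#' @param fs Named list of sampling rates per modality (Hz).
#' @param noise_sd Named list of additive noise levels: `ecg` and `emg` in
#'   device units, `eda` in microsiemens, `resp` relative to the unit
#'   breathing amplitude.
#' @param tech Technology arm label stored on the simulated session.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       duration_s = 600,
                       protocol = c("free_breathing", "breathwork_478"),
                       base_breath_rate_bpm = 15,
                       breath_rate_trajectory = NULL,
                       cycle_jitter_sd = 0.05,
                       breathwork_leadin_s = 60,
                       mean_hr_bpm = 70,
                       rr_modulation = tibble::tibble(freq_hz = c(0.1, 0.3),
                                                      amplitude_s = c(0.03, 0.02)),
                       rr_noise_sd_s = 0.01,
                       eda_tonic_trajectory = tibble::tibble(time_s = c(0, 600),
                                                             uS = c(5, 6)),
                       scr_rate_per_min = 4,
                       scr_amplitude_uS = 0.5,
                       artifact_windows = NULL,
                       fs = list(ecg = 500, eda = 32, emg = 100, resp = 25),
                       noise_sd = list(ecg = 20, resp = 0.05, eda = 0.01, emg = 10),
                       tech = "MindGym") {
  protocol <- match.arg(protocol)
  stopifnot(duration_s > 0, mean_hr_bpm > 0, base_breath_rate_bpm > 0,
            all(unlist(fs) > 0), cycle_jitter_sd >= 0)
  if (!is.null(breath_rate_trajectory)) {
    breath_rate_trajectory <- tibble::as_tibble(breath_rate_trajectory)
    stopifnot(all(c("time_s", "bpm") %in% names(breath_rate_trajectory)))
    if (any(breath_rate_trajectory$bpm <= 0)) {
      stop("breath rate trajectory must stay strictly positive")
    }
  }
  if (!is.null(artifact_windows)) {
    artifact_windows <- tibble::as_tibble(artifact_windows)
    stopifnot(all(c("start_s", "duration_s", "gain") %in% names(artifact_windows)))
    if (any(artifact_windows$start_s < 0) ||
        any(artifact_windows$start_s + artifact_windows$duration_s > duration_s)) {
      stop("artifact windows must lie within [0, duration_s]")
    }
  }
  structure(
    list(seed = as.integer(seed), duration_s = duration_s, protocol = protocol,
         base_breath_rate_bpm = base_breath_rate_bpm,
         breath_rate_trajectory = breath_rate_trajectory,
         cycle_jitter_sd = cycle_jitter_sd,
         breathwork_leadin_s = breathwork_leadin_s,
         mean_hr_bpm = mean_hr_bpm, rr_modulation = tibble::as_tibble(rr_modulation),
         rr_noise_sd_s = rr_noise_sd_s,
         eda_tonic_trajectory = tibble::as_tibble(eda_tonic_trajectory),
         scr_rate_per_min = scr_rate_per_min, scr_amplitude_uS = scr_amplitude_uS,
         artifact_windows = artifact_windows, fs = fs, noise_sd = noise_sd,
         tech = tech),
    class = "sim_config"
  )
}

# Piecewise-linear breath rate (bpm) at time t for a config.
breath_rate_at <- function(cfg, t) {
  if (is.null(cfg$breath_rate_trajectory)) {
    rep(cfg$base_breath_rate_bpm, length(t))
  } else {
    interp_lin(cfg$breath_rate_trajectory$time_s, cfg$breath_rate_trajectory$bpm, t)
  }
}

# One breathing cycle rendered on a phase axis: returns value in [-1, 1].
# Free breathing: rising half-cosine over the first 40% (inhale), falling
# over the rest (exhale). 4-7-8: rise 4/19, plateau 7/19, fall 8/19.
cycle_waveform <- function(u, kind, frac = c(4, 7, 8) / 19) {
  v <- numeric(length(u))
  if (kind == "free") {
    inh <- u < 0.4
    v[inh] <- -cos(pi * u[inh] / 0.4)
    v[!inh] <- cos(pi * (u[!inh] - 0.4) / 0.6)
  } else {
    b1 <- frac[1]; b2 <- frac[1] + frac[2]
    i1 <- u < b1; i2 <- u >= b1 & u < b2; i3 <- u >= b2
    v[i1] <- -cos(pi * u[i1] / b1)
    v[i2] <- 1
    v[i3] <- cos(pi * (u[i3] - b2) / (1 - b2))
  }
  v
}

#' Simulate a respiration channel with ground-truth breath onsets
#'
#' Renders breathing as a smooth periodic waveform (unit amplitude,
#' arbitrary units): free breathing follows the configured rate trajectory
#' with a half-cosine inhale over 40% of the cycle; the 4-7-8 protocol is a
#' rising ramp (4 s), plateau (7 s) and falling ramp (8 s) per 19 s cycle,
#' preceded by a free-breathing lead-in. Inhalation onsets are the ramp
#' starts; exhalation onsets the start of the fall. Gaussian noise is added
#' at the configured level.
#'
#' @param cfg A [sim_config()].
#' @return List with `channel` (a RESP [channel()]) and `truth` (list with
#'   `breaths` tibble: `inh_s`, `exh_s`, `duration_s`).
#' @export
simulate_respiration <- function(cfg) {
  cycles <- simulate_breath_cycles(cfg)
  dur <- cfg$duration_s
  fs <- cfg$fs$resp
  ch <- with_seed(cfg$seed + 151L, {
    tt <- seq(0, dur, by = 1 / fs)
    v <- numeric(length(tt))
    for (i in seq_len(nrow(cycles))) {
      idx <- which(tt >= cycles$t0[i] & tt < cycles$t0[i] + cycles$len[i])
      if (!length(idx)) next
      u <- (tt[idx] - cycles$t0[i]) / cycles$len[i]
      v[idx] <- cycle_waveform(u, cycles$kind[i])
    }
    v <- v + stats::rnorm(length(v), 0, cfg$noise_sd$resp)
    channel(tt, v, "RESP", fs, units = "a.u.")
  })
  # a breath counts only when its exhalation onset falls inside the
  # session (the same inhalation->exhalation pairing rule the detector
  # applies; a trailing incomplete cycle is not a breath)
  breaths <- cycles[cycles$t0 < dur & cycles$exh < dur, ]
  list(channel = ch,
       truth = list(breaths = tibble::tibble(inh_s = breaths$t0,
                                             exh_s = breaths$exh,
                                             duration_s = breaths$len)))
}

# Seeded breath-cycle generator shared by the waveform renderer and the
# ground-truth-only path.
simulate_breath_cycles <- function(cfg) {
  with_seed(cfg$seed + 101L, {
    dur <- cfg$duration_s
    t0 <- numeric(0); len <- numeric(0); exh <- numeric(0); kind <- character(0)
    t <- 0
    repeat {
      if (t >= dur) break
      paced <- cfg$protocol == "breathwork_478" && t >= cfg$breathwork_leadin_s
      jit <- exp(stats::rnorm(1, 0, cfg$cycle_jitter_sd))
      if (paced) {
        clen <- 19 * jit
        eoff <- 11 / 19 * clen
        k <- "paced"
      } else {
        rate <- breath_rate_at(cfg, t)
        if (rate <= 0) stop("breath rate trajectory reached a non-positive value")
        clen <- 60 / rate * jit
        eoff <- 0.4 * clen
        k <- "free"
      }
      t0 <- c(t0, t); len <- c(len, clen); exh <- c(exh, t + eoff); kind <- c(kind, k)
      t <- t + clen
    }
    tibble::tibble(t0 = t0, len = len, exh = exh, kind = kind)
  })
}

#' Ground-truth breath events without rendering a waveform
#'
#' Generates the same seeded breath cycles as [simulate_respiration()] and
#' returns them directly as a `breath_events` object. Useful when only the
#' true windowed breath rates are needed (e.g. statistical power studies
#' over many simulated cohorts).
#'
#' @param cfg A [sim_config()].
#' @return A `breath_events` object.
#' @export
simulate_breath_events <- function(cfg) {
  cycles <- simulate_breath_cycles(cfg)
  b <- cycles[cycles$t0 < cfg$duration_s & cycles$exh < cfg$duration_s, ]
  new_breath_events(
    breaths = tibble::tibble(inh_s = b$t0, exh_s = b$exh,
                             amplitude = rep(2, nrow(b))),
    inhalation_onsets_s = b$t0, exhalation_onsets_s = b$exh
  )
}

#' Simulate a cohort's windowed breath-rate features
#'
#' Draws `n_per_cell` subjects for each of the four study cells (MindGym/VR
#' crossed with Breathwork/Rain), gives every subject an individual
#' free-breathing base rate from a normal distribution, generates their
#' seeded ground-truth breath events (Breathwork subjects switch to 4-7-8
#' pacing after the lead-in; Rain subjects breathe freely throughout), and
#' returns the five 2-minute breath-rate timepoints per subject. The
#' technology factor carries no physiological effect — it is a built-in
#' null.
#'
#' @param n_per_cell Subjects per tech-by-stim cell.
#' @param seed Cohort seed (subject seeds are derived from it).
#' @param base_rate_mean_bpm,base_rate_sd_bpm Between-subject distribution
#'   of the free-breathing rate.
#' @return Feature tibble with `participant_id`, `tech`, `stim`,
#'   `BR_t1`..`BR_t5`.
#' @export
simulate_breath_cohort <- function(n_per_cell = 20, seed = 1L,
                                   base_rate_mean_bpm = 15,
                                   base_rate_sd_bpm = 2) {
  cells <- expand.grid(tech = c("MindGym", "VR"), stim = c("Breathwork", "Rain"),
                       stringsAsFactors = FALSE)
  rows <- list()
  sid <- 0L
  for (ci in seq_len(nrow(cells))) {
    for (j in seq_len(n_per_cell)) {
      sid <- sid + 1L
      subj_seed <- (seed * 10007L + sid) %% 2000000000L
      base <- with_seed(subj_seed, {
        max(8, stats::rnorm(1, base_rate_mean_bpm, base_rate_sd_bpm))
      })
      cfg <- sim_config(
        seed = subj_seed,
        protocol = if (cells$stim[ci] == "Breathwork") "breathwork_478" else "free_breathing",
        base_breath_rate_bpm = base, tech = cells$tech[ci]
      )
      ev <- simulate_breath_events(cfg)
      br <- breath_rate_series(ev)
      rows[[sid]] <- tibble::tibble(
        participant_id = sprintf("s%04d", sid),
        tech = cells$tech[ci], stim = cells$stim[ci],
        BR_t1 = br$rates$rate_bpm[1], BR_t2 = br$rates$rate_bpm[2],
        BR_t3 = br$rates$rate_bpm[3], BR_t4 = br$rates$rate_bpm[4],
        BR_t5 = br$rates$rate_bpm[5]
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Simulate an ECG channel with ground-truth R-peak times
#'
#' RR intervals follow `60/mean_hr_bpm` plus the configured sinusoidal
#' modulation components and white RR noise. The waveform is a flat baseline
#' with a fixed sharp biphasic template (80 ms, apex +800 device units)
#' placed at each R-peak time, plus Gaussian noise. Morphological realism
#' (P/T waves) is deliberately out of scope: the template's sharp apex is
#' what R-peak detection needs.
#'
#' @param cfg A [sim_config()].
#' @return List with `channel` (an ECG [channel()]) and `truth` (list with
#'   `r_peaks_s`, the apex times snapped to the sampling grid).
#' @export
simulate_ecg <- function(cfg) {
  with_seed(cfg$seed + 202L, {
    dur <- cfg$duration_s
    mean_rr <- 60 / cfg$mean_hr_bpm
    if (nrow(cfg$rr_modulation) &&
        mean_rr <= sum(abs(cfg$rr_modulation$amplitude_s))) {
      stop("summed RR modulation amplitudes must be smaller than the mean RR interval")
    }
    t <- 0.3
    peaks <- numeric(0)
    while (t < dur) {
      peaks <- c(peaks, t)
      rr <- mean_rr
      if (nrow(cfg$rr_modulation)) {
        rr <- rr + sum(cfg$rr_modulation$amplitude_s *
                         sin(2 * pi * cfg$rr_modulation$freq_hz * t))
      }
      rr <- rr + stats::rnorm(1, 0, cfg$rr_noise_sd_s)
      if (rr <= 0) stop("RR modulation produced a non-positive interval")
      t <- t + rr
    }
    fs <- cfg$fs$ecg
    tt <- seq(0, dur, by = 1 / fs)
    v <- stats::rnorm(length(tt), 0, cfg$noise_sd$ecg)
    # biphasic template: 20 ms rise to +800, 30 ms fall to -150, 30 ms return
    n_rise <- max(2L, round(0.020 * fs)); n_fall <- max(2L, round(0.030 * fs))
    tpl <- c(seq(0, 800, length.out = n_rise + 1L)[-1L],
             seq(800, -150, length.out = n_fall + 1L)[-1L],
             seq(-150, 0, length.out = n_fall + 1L)[-1L])
    apex <- n_rise  # index of +800 within tpl
    snapped <- numeric(length(peaks))
    for (i in seq_along(peaks)) {
      k <- round(peaks[i] * fs) + 1L  # grid index of apex
      snapped[i] <- tt[min(k, length(tt))]
      lo <- k - apex + 1L
      idx <- seq(lo, lo + length(tpl) - 1L)
      ok <- idx >= 1L & idx <= length(v)
      v[idx[ok]] <- v[idx[ok]] + tpl[ok]
    }
    list(channel = channel(tt, v, "ECG", fs, units = "mV"),
         truth = list(r_peaks_s = snapped))
  })
}

#' Simulate coupled EDA and EMG channels with ground-truth artifacts
#'
#' EDA is the piecewise-linear tonic trajectory plus Poisson-timed phasic
#' responses (1 s half-cosine rise, exponential decay) and Gaussian noise.
#' EMG is zero-mean Gaussian noise whose amplitude is multiplied by the
#' configured gain inside each motion-artifact window; inside the same
#' windows the EDA additionally receives white spiky contamination scaled by
#' the gain. Overlapping windows are merged.
#'
#' @param cfg A [sim_config()].
#' @return List with `eda`, `emg` (channels) and `truth` (list with
#'   `artifact_windows` tibble, `scr_times_s`, and `tonic_at`, a function of
#'   time returning the true tonic level).
#' @export
simulate_eda_emg <- function(cfg) {
  dur <- cfg$duration_s
  win <- if (is.null(cfg$artifact_windows)) {
    tibble::tibble(start_s = numeric(), end_s = numeric(), gain = numeric())
  } else {
    tibble::tibble(start_s = cfg$artifact_windows$start_s,
                   end_s = cfg$artifact_windows$start_s + cfg$artifact_windows$duration_s,
                   gain = cfg$artifact_windows$gain)
  }
  merged <- merge_intervals(win)
  traj <- cfg$eda_tonic_trajectory
  tonic_at <- function(t) interp_lin(traj$time_s, traj$uS, t)

  eda <- with_seed(cfg$seed + 303L, {
    fs <- cfg$fs$eda
    tt <- seq(0, dur, by = 1 / fs)
    v <- tonic_at(tt)
    # Poisson SCR train
    scr_times <- numeric(0)
    if (cfg$scr_rate_per_min > 0) {
      t <- 0
      repeat {
        t <- t + stats::rexp(1, rate = cfg$scr_rate_per_min / 60)
        if (t > dur) break
        scr_times <- c(scr_times, t)
      }
    }
    if (length(scr_times)) {
      kt <- seq(0, 7, by = 1 / fs)  # 1 s rise + decay tail
      kernel <- ifelse(kt < 1, (1 - cos(pi * kt)) / 2, exp(-(kt - 1) / (4 / 3)))
      kernel <- cfg$scr_amplitude_uS * kernel
      for (ts in scr_times) {
        k0 <- round(ts * fs) + 1L
        idx <- seq(k0, min(k0 + length(kernel) - 1L, length(v)))
        v[idx] <- v[idx] + kernel[seq_along(idx)]
      }
    }
    if (cfg$noise_sd$eda > 0) v <- v + stats::rnorm(length(v), 0, cfg$noise_sd$eda)
    if (nrow(win)) {
      for (i in seq_len(nrow(win))) {
        idx <- which(tt >= win$start_s[i] & tt <= win$end_s[i])
        v[idx] <- v[idx] + stats::rnorm(length(idx), 0, 0.2 * win$gain[i])
      }
    }
    list(ch = channel(tt, v, "EDA", fs, units = "uS"), scr_times = scr_times)
  })

  emg <- with_seed(cfg$seed + 404L, {
    fs <- cfg$fs$emg
    tt <- seq(0, dur, by = 1 / fs)
    g <- rep(1, length(tt))
    if (nrow(win)) {
      for (i in seq_len(nrow(win))) {
        g[tt >= win$start_s[i] & tt <= win$end_s[i]] <- win$gain[i]
      }
    }
    v <- stats::rnorm(length(tt), 0, cfg$noise_sd$emg) * g
    channel(tt, v, "EMG", fs, units = "mV")
  })

  list(eda = eda$ch, emg = emg,
       truth = list(artifact_windows = merged, scr_times_s = eda$scr_times,
                    tonic_at = tonic_at))
}

#' Simulate a full multimodal session with ground truth
#'
#' Assembles respiration, ECG, EDA and EMG channels into one
#' [session_recording()] with `experience_start`/`experience_end` markers at
#' t = 0 and t = `duration_s`. The breathwork protocol produces the
#' designed first-to-last-window breath-rate decrease (free-breathing
#' lead-in, then 4-7-8 pacing at about 3.2 breaths/min); free breathing
#' stays flat, mirroring the contrast the pipeline is meant to detect.
#'
#' @param cfg A [sim_config()].
#' @param participant_id Identifier stored on the session.
#' @return List with `session` (a `physio_session`) and `truth` (list
#'   combining the sub-simulators' ground truth).
#' @export
simulate_session <- function(cfg, participant_id = sprintf("sim%04d", cfg$seed)) {
  resp <- simulate_respiration(cfg)
  ecg <- simulate_ecg(cfg)
  ee <- simulate_eda_emg(cfg)
  markers <- tibble::tibble(label = c("experience_start", "experience_end"),
                            time_s = c(0, cfg$duration_s))
  stim <- if (cfg$protocol == "breathwork_478") "Breathwork" else "Rain"
  rec <- session_recording(
    participant_id,
    list(ECG = ecg$channel, EDA = ee$eda, EMG = ee$emg, RESP = resp$channel),
    markers, tech = cfg$tech, stim = stim
  )
  list(session = rec,
       truth = list(breaths = resp$truth$breaths,
                    r_peaks_s = ecg$truth$r_peaks_s,
                    artifact_windows = ee$truth$artifact_windows,
                    scr_times_s = ee$truth$scr_times_s,
                    tonic_at = ee$truth$tonic_at))
}

#' Breath events from simulator ground truth
#'
#' Converts the simulator's true breath table into the same `breath_events`
#' container the respiration detector produces, so windowed rates and QA
#' verdicts can be computed directly from ground truth.
#'
#' @param truth The `truth` element returned by [simulate_respiration()] or
#'   [simulate_session()].
#' @return A `breath_events` object (see [detect_breath_onsets()]).
#' @export
ground_truth_breath_events <- function(truth) {
  b <- truth$breaths
  new_breath_events(
    breaths = tibble::tibble(inh_s = b$inh_s, exh_s = b$exh_s,
                             amplitude = rep(2, nrow(b))),
    inhalation_onsets_s = b$inh_s,
    exhalation_onsets_s = b$exh_s
  )
}
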