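#' Run the full processing pipeline over sessions
#'
#' For each session: trims to the experience markers, then per modality —
#' ECG is cleaned (notch, bandpass, amplitude gate), checked for baseline
#' wandering, and R peaks feed the per-minute heart rate and first/last
#' 5-minute LF/HF; EMG drives motion-artifact detection; EDA is cleaned,
#' scored with the 0-100 quality index (rejected below 50) and summarized
#' as 2-minute tonic means; respiration is smoothed, breath onsets
#' detected, 2-minute rates computed and the under-20-breaths/min gate
#' applied. A modality failing any acceptability rule leaves its feature
#' columns missing with the exclusion recorded, mirroring per-modality
#' availability in real cohorts. Sessions that fail to process are logged
#' and skipped; the run errors only when no session is usable.
#'
#' @param sessions List of [session_recording()] objects.
#' @param ecg,eda,resp,hrv Per-module parameter lists.
#' @param out_dir Optional output directory for [write_outputs()].
#' @param overwrite Passed to [write_outputs()].
#' @return List of class `physio_run`: `features` (tibble, one row per
#'   usable participant), `qc` (list of per-channel records), `skipped`
#'   (tibble of skipped sessions and reasons), `manifest`.
#' @export
run_pipeline <- function(sessions, ecg = ecg_params(), eda = eda_params(),
                         resp = resp_params(), hrv = hrv_params(),
                         out_dir = NULL, overwrite = FALSE) {
  stopifnot(length(sessions) >= 1L)
  feats <- list(); qc <- list(); skipped <- list()
  for (rec in sessions) {
    res <- tryCatch(process_session(rec, ecg, eda, resp, hrv),
                    error = function(e) e)
    if (inherits(res, "error")) {
      skipped[[length(skipped) + 1L]] <-
        tibble::tibble(participant_id = rec$participant_id,
                       reason = conditionMessage(res))
      next
    }
    feats[[length(feats) + 1L]] <- res$features
    qc[[rec$participant_id]] <- res$qc
  }
  if (!length(feats)) stop("no usable sessions: all failed to process")
  features <- dplyr::bind_rows(feats)
  skipped <- if (length(skipped)) dplyr::bind_rows(skipped) else
    tibble::tibble(participant_id = character(), reason = character())
  manifest <- list(
    n_sessions = length(sessions),
    n_usable = nrow(features),
    n_skipped = nrow(skipped),
    params_fingerprint = params_fingerprint(list(ecg = unclass(ecg),
                                                 eda = unclass(eda),
                                                 resp = unclass(resp),
                                                 hrv = unclass(hrv)))
  )
  out <- structure(list(features = features, qc = qc, skipped = skipped,
                        manifest = manifest),
                   class = "physio_run")
  if (!is.null(out_dir)) write_outputs(features, qc, out_dir, overwrite = overwrite)
  out
}

# Stable fingerprint of the parameter set (md5 of its serialized form).
params_fingerprint <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

# One session through every modality; returns features row + QC records.
process_session <- function(rec, ecg_p, eda_p, resp_p, hrv_p) {
  rec <- trim_to_experience(rec)
  span <- marker_time(rec, "experience_end")
  qc <- list()
  exclusions <- character(0)

  hr <- NULL; hrv_tab <- NULL
  if (!is.null(rec$channels$ECG)) {
    cl <- clean_ecg(rec$channels$ECG, ecg_p)
    acc <- assess_ecg_acceptability(rec$channels$ECG, ecg_p)
    qc$ECG <- list(modality = "ECG", wander = acc$wander,
                   masked_fraction = cl$masked_fraction,
                   verdict = if (acc$acceptable && cl$acceptable) "acceptable" else "unacceptable")
    if (acc$acceptable && cl$acceptable) {
      rp <- detect_r_peaks(cl$channel)
      qc$ECG$n_peaks <- nrow(rp)
      if (attr(rp, "acceptable")) {
        hr <- heart_rate_series(rp, span_s = span)
        hrv_tab <- hrv_first_last(rp, span_s = span, params = hrv_p)
      } else {
        exclusions["ECG"] <- "too few R peaks detected"
        qc$ECG$verdict <- "unacceptable"
      }
    } else {
      exclusions["ECG"] <- if (!acc$acceptable) "baseline wandering above threshold" else
        "amplitude gate masked most of the channel"
    }
  } else exclusions["ECG"] <- "modality absent"

  eda_tonic <- NULL
  if (!is.null(rec$channels$EDA)) {
    win <- detect_motion_windows(rec$channels$EMG, eda_p)
    cl <- clean_eda(rec$channels$EDA, win, eda_p)
    qi <- eda_quality_index(cl$channel, eda_p)
    qc$EDA <- list(modality = "EDA", qi = qi$qi,
                   artifact_window_count = nrow(win$intervals),
                   artifact_coverage_fraction = cl$artifact_coverage,
                   emg_note = win$note,
                   verdict = if (qi$acceptable && cl$acceptable) "acceptable" else "unacceptable")
    if (qi$acceptable && cl$acceptable) {
      eda_tonic <- tonic_series(cl$channel, eda_p, span_s = span)
    } else {
      exclusions["EDA"] <- if (!qi$acceptable) "quality index below threshold" else
        "artifact windows cover most of the channel"
    }
  } else exclusions["EDA"] <- "modality absent"

  breath <- NULL
  if (!is.null(rec$channels$RESP)) {
    sm <- smooth_respiration(rec$channels$RESP, resp_p)
    ev <- detect_breath_onsets(sm, resp_p)
    br <- breath_rate_series(ev, resp_p, span_s = span)
    qc$RESP <- list(modality = "RESP", mean_rate_bpm = br$mean_rate_bpm,
                    n_breaths = nrow(ev$breaths),
                    qa_verdict = if (br$qa_pass) "acceptable" else "unacceptable",
                    notes = c(sm$notes, ev$notes))
    if (br$qa_pass) breath <- br else
      exclusions["RESP"] <- "mean breath rate at or above the QA maximum"
  } else exclusions["RESP"] <- "modality absent"

  features <- assemble_features(rec$participant_id, breath = breath, hr = hr,
                                eda_tonic = eda_tonic, hrv = hrv_tab,
                                tech = rec$tech, stim = rec$stim,
                                exclusions = exclusions)
  list(features = features, qc = qc)
}

#' Statistical analysis of a feature table
#'
#' Fits the configured mixed repeated-measures ANOVA models per
#' physiological measure, corrects the resulting p-values by
#' Benjamini-Hochberg within each measure (across the models' effects), and
#' tests group differences in the change scores (last minus first
#' timepoint) with Mann-Whitney U per between factor, FDR-corrected within
#' each comparison family.
#'
#' @param features Feature table from [run_pipeline()]/[assemble_features()].
#' @param measures Which physiological measures to analyze.
#' @param models Which rmANOVA designs to fit per measure.
#' @return List of class `physio_stats`: `rm_anova` (tibble of effects with
#'   `p_fdr`), `group_tests` (tibble), `fits` (named list of `rm_anova`
#'   objects).
#' @export
analyze_features <- function(features,
                             measures = c("BR", "HR", "EDA", "HRV"),
                             models = c("time_only", "time_by_tech",
                                        "time_by_stim", "time_by_tech_by_stim")) {
  fits <- list()
  rows <- list()
  for (ms in measures) {
    long <- features_long(features, ms)
    long <- long[!is.na(long$value), ]
    if (!nrow(long)) next
    for (md in models) {
      fit <- tryCatch(rm_anova_gg(long, md), error = function(e) NULL)
      if (is.null(fit)) next
      fits[[paste(ms, md, sep = ".")]] <- fit
      tab <- fit$table
      tab$measure <- ms
      tab$model <- md
      rows[[length(rows) + 1L]] <- tab
    }
  }
  rm_tab <- if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble()
  if (nrow(rm_tab)) rm_tab$p_fdr <- fdr_bh(rm_tab$p_corrected, rm_tab$measure)

  gt <- list()
  change_cols <- c(BR = "BR_change", HR = "HR_change", HRV = "HRV_change")
  for (ms in intersect(measures, names(change_cols))) {
    v <- features[[change_cols[[ms]]]]
    if (is.null(v)) next
    for (fac in c("tech", "stim")) {
      lv <- unique(stats::na.omit(features[[fac]]))
      if (length(lv) != 2L) next
      x <- v[features[[fac]] == lv[1]]
      y <- v[features[[fac]] == lv[2]]
      if (sum(!is.na(x)) < 3L || sum(!is.na(y)) < 3L) next
      res <- mann_whitney_rbc(x, y)
      res$measure <- ms
      res$comparison <- paste(fac, ":", lv[1], "vs", lv[2])
      gt[[length(gt) + 1L]] <- res
    }
  }
  gt <- if (length(gt)) dplyr::bind_rows(gt) else tibble::tibble()
  if (nrow(gt)) gt$p_fdr <- fdr_bh(gt$p_raw, gt$comparison)

  structure(list(rm_anova = rm_tab, group_tests = gt, fits = fits),
            class = "physio_stats")
}
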