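feature_columns <- function() {
  c(paste0("BR_t", 1:5), paste0("HR_t", 1:10), paste0("EDA_t", 1:5),
    "HRV_first", "HRV_last")
}

derived_columns <- function() {
  c("BR_initial", "BR_change", "HR_initial", "HR_change",
    "HRV_initial", "HRV_change")
}

#' Assemble one participant's physiological feature row
#'
#' Lays out the windowed dependent variables — five 2-minute breath rates,
#' ten 1-minute heart rates, five 2-minute tonic EDA means and the first/last
#' 5-minute LF/HF ratios — plus the derived covariates (initial value and
#' last-minus-first change per modality) and per-modality acceptability
#' flags. A rejected modality leaves its columns missing (`NA`, written as
#' empty cells — a windowed mean of zero is physiologically meaningful and
#' must never collide with missingness) and records the exclusion reason.
#'
#' @param participant_id Identifier.
#' @param breath A `breath_rates` object, or `NULL` when respiration was
#'   rejected/absent.
#' @param hr Tibble from [heart_rate_series()], or `NULL`.
#' @param eda_tonic Tibble from [tonic_series()], or `NULL`.
#' @param hrv Tibble from [hrv_first_last()], or `NULL`.
#' @param tech,stim Group labels.
#' @param exclusions Named character vector of exclusion reasons keyed by
#'   modality (e.g. `c(EDA = "quality index below 50")`).
#' @return One-row tibble with the fixed column order: identifiers and
#'   groups, 22 feature columns, 6 derived covariates, acceptability flags
#'   and the exclusion note. Errors when every modality was rejected.
#' @export
assemble_features <- function(participant_id, breath = NULL, hr = NULL,
                              eda_tonic = NULL, hrv = NULL,
                              tech = NA_character_, stim = NA_character_,
                              exclusions = character(0)) {
  if (is.null(breath) && is.null(hr) && is.null(eda_tonic) && is.null(hrv)) {
    stop("participant ", participant_id, " excluded: all modalities rejected (",
         paste(names(exclusions), exclusions, sep = ": ", collapse = "; "), ")")
  }
  take <- function(v, n) { out <- rep(NA_real_, n); out[seq_len(min(length(v), n))] <- v[seq_len(min(length(v), n))]; out }
  br <- if (!is.null(breath)) take(breath$rates$rate_bpm, 5) else rep(NA_real_, 5)
  hrv10 <- if (!is.null(hr)) take(hr$hr_bpm, 10) else rep(NA_real_, 10)
  eda5 <- if (!is.null(eda_tonic)) take(eda_tonic$tonic_uS, 5) else rep(NA_real_, 5)
  hrv2 <- if (!is.null(hrv)) {
    c(first = hrv$lf_hf_ratio[hrv$segment == "first_5min"][1],
      last = hrv$lf_hf_ratio[hrv$segment == "last_5min"][1])
  } else c(first = NA_real_, last = NA_real_)
  row <- tibble::tibble(
    participant_id = participant_id, tech = tech, stim = stim
  )
  feats <- c(br, hrv10, eda5, hrv2)
  names(feats) <- feature_columns()
  row <- dplyr::bind_cols(row, tibble::as_tibble(as.list(feats)))
  row$BR_initial <- row$BR_t1
  row$BR_change <- row$BR_t5 - row$BR_t1
  row$HR_initial <- row$HR_t1
  row$HR_change <- row$HR_t10 - row$HR_t1
  row$HRV_initial <- row$HRV_first
  row$HRV_change <- row$HRV_last - row$HRV_first
  row$resp_ok <- !is.null(breath)
  row$ecg_ok <- !is.null(hr) || !is.null(hrv)
  row$eda_ok <- !is.null(eda_tonic)
  row$exclusions <- if (length(exclusions)) {
    paste(names(exclusions), exclusions, sep = ": ", collapse = "; ")
  } else ""
  row
}

#' Pivot a feature table to the long analysis layout
#'
#' Converts one physiological measure's windowed columns to the long
#' (participant, tech, stim, timepoint, value) layout the repeated-measures
#' ANOVA consumes.
#'
#' @param features Feature table from [assemble_features()] rows.
#' @param measure One of `"BR"`, `"HR"`, `"EDA"`, `"HRV"`.
#' @return Long tibble with `participant`, `tech`, `stim`, `timepoint`
#'   (integer), `value`.
#' @export
features_long <- function(features, measure = c("BR", "HR", "EDA", "HRV")) {
  measure <- match.arg(measure)
  cols <- switch(measure,
                 BR = paste0("BR_t", 1:5),
                 HR = paste0("HR_t", 1:10),
                 EDA = paste0("EDA_t", 1:5),
                 HRV = c("HRV_first", "HRV_last"))
  long <- tidyr::pivot_longer(
    features[, c("participant_id", "tech", "stim", cols)],
    dplyr::all_of(cols), names_to = "timepoint", values_to = "value"
  )
  long$timepoint <- match(long$timepoint, cols)
  dplyr::rename(long, participant = "participant_id")
}
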