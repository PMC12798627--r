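#' Load a multimodal session recording
#'
#' Reads the package's plain-text session dialect: a directory containing
#' one CSV per channel (comment header lines `# modality:`, `# fs:`,
#' `# units:`, then `time_s,value` rows) and a `*markers.csv` sidecar with
#' `label,time_s` rows (optionally `# participant_id:`, `# tech:`,
#' `# stim:` headers). Streams are matched to modalities by
#' case-insensitive substring match of the pattern against the file name or
#' the declared modality label; a modality matching no stream is recorded
#' as absent (not an error), while a pattern matching two streams raises an
#' ambiguity error naming both. Timestamps are kept in seconds relative to
#' recording start.
#'
#' Binary XDF containers are not read directly; export each stream to this
#' dialect first (an `.xdf` path raises a load error saying so).
#'
#' @param path Directory containing one session's channel files.
#' @param stream_spec Named list/character vector mapping modality to a
#'   name/label pattern.
#' @param participant_id Overrides the identifier from the sidecar/path.
#' @return A [session_recording()].
#' @export
load_session <- function(path,
                         stream_spec = c(ECG = "ecg", EDA = "eda",
                                         EMG = "emg", RESP = "resp"),
                         participant_id = NULL) {
  if (grepl("\\.xdf$", path, ignore.case = TRUE)) {
    stop("binary XDF containers are not read directly; export streams to the ",
         "CSV session dialect (see ?load_session)")
  }
  if (!dir.exists(path)) stop("cannot read session: no such directory: ", path)
  files <- list.files(path, pattern = "\\.csv$", full.names = TRUE)
  marker_files <- files[grepl("markers", basename(files), ignore.case = TRUE)]
  chan_files <- setdiff(files, marker_files)
  if (!length(chan_files)) stop("cannot read session: no channel CSV files in ", path)

  parse_header <- function(file) {
    lines <- readLines(file, n = 10L)
    hdr <- lines[startsWith(lines, "#")]
    get <- function(key) {
      hit <- grep(paste0("^#\\s*", key, "\\s*:"), hdr, value = TRUE)
      if (!length(hit)) return(NA_character_)
      trimws(sub("^#[^:]*:", "", hit[1]))
    }
    list(modality = get("modality"), fs = suppressWarnings(as.numeric(get("fs"))),
         units = get("units"), participant_id = get("participant_id"),
         tech = get("tech"), stim = get("stim"))
  }

  headers <- lapply(chan_files, parse_header)
  channels <- list()
  for (modality in names(stream_spec)) {
    pat <- tolower(stream_spec[[modality]])
    hit <- which(vapply(seq_along(chan_files), function(i) {
      grepl(pat, tolower(basename(chan_files[i])), fixed = TRUE) ||
        (!is.na(headers[[i]]$modality) &&
           grepl(pat, tolower(headers[[i]]$modality), fixed = TRUE))
    }, logical(1)))
    if (length(hit) > 1L) {
      stop("stream pattern '", stream_spec[[modality]], "' for modality ",
           modality, " matches several streams: ",
           paste(basename(chan_files[hit]), collapse = ", "))
    }
    if (!length(hit)) next  # absent modality
    f <- chan_files[hit]
    h <- headers[[hit]]
    dat <- utils::read.csv(f, comment.char = "#")
    if (!all(c("time_s", "value") %in% names(dat))) {
      stop("corrupt channel file (need time_s,value columns): ", f)
    }
    fs <- if (is.finite(h$fs)) h$fs else 1 / stats::median(diff(dat$time_s))
    channels[[toupper(modality)]] <-
      channel(dat$time_s, dat$value, toupper(modality), fs,
              units = if (is.na(h$units)) "" else h$units)
  }
  markers <- tibble::tibble(label = character(), time_s = numeric())
  meta <- list(participant_id = NA_character_, tech = NA_character_, stim = NA_character_)
  if (length(marker_files)) {
    mh <- parse_header(marker_files[1])
    meta$participant_id <- mh$participant_id
    meta$tech <- mh$tech
    meta$stim <- mh$stim
    md <- utils::read.csv(marker_files[1], comment.char = "#")
    markers <- tibble::tibble(label = as.character(md$label),
                              time_s = as.numeric(md$time_s))
  }
  pid <- participant_id %||% meta$participant_id
  if (is.null(pid) || is.na(pid)) pid <- basename(normalizePath(path))
  session_recording(pid, channels, markers, tech = meta$tech, stim = meta$stim)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Write a session recording in the CSV session dialect
#'
#' One `<participant>_<MODALITY>.csv` per channel plus a
#' `<participant>_markers.csv` sidecar, round-trippable through
#' [load_session()] to decimal-text precision.
#'
#' @param rec A [session_recording()].
#' @param dir Output directory (created if needed).
#' @param overwrite Refuse to clobber existing files unless `TRUE`.
#' @return Invisibly, the written file paths.
#' @export
write_session_csv <- function(rec, dir, overwrite = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  for (m in names(rec$channels)) {
    ch <- rec$channels[[m]]
    f <- file.path(dir, sprintf("%s_%s.csv", rec$participant_id, m))
    if (file.exists(f) && !overwrite) stop("refusing to overwrite ", f)
    con <- file(f, "w")
    writeLines(c(sprintf("# modality: %s", m),
                 sprintf("# fs: %.10g", channel_fs(ch)),
                 sprintf("# units: %s", channel_units(ch))), con)
    utils::write.csv(as.data.frame(ch)[, c("time_s", "value")], con,
                     row.names = FALSE, quote = FALSE)
    close(con)
    written <- c(written, f)
  }
  f <- file.path(dir, sprintf("%s_markers.csv", rec$participant_id))
  if (file.exists(f) && !overwrite) stop("refusing to overwrite ", f)
  con <- file(f, "w")
  writeLines(c(sprintf("# participant_id: %s", rec$participant_id),
               sprintf("# tech: %s", rec$tech),
               sprintf("# stim: %s", rec$stim)), con)
  utils::write.csv(as.data.frame(rec$markers), con, row.names = FALSE, quote = FALSE)
  close(con)
  invisible(c(written, f))
}

#' Write the feature table and QC report
#'
#' The feature table is tab-separated, one row per participant, with the
#' fixed column order (identifiers/groups, `BR_t1..BR_t5`, `HR_t1..HR_t10`,
#' `EDA_t1..EDA_t5`, `HRV_first`, `HRV_last`, derived covariates,
#' per-modality acceptability flags); missing values are empty cells. The
#' QC report is JSON, one record per channel with the verdict, quality
#' index / wander value and artifact-window count.
#'
#' @param features Feature tibble ([assemble_features()] rows).
#' @param qc List of per-channel QC records (see [run_pipeline()]).
#' @param out_dir Output directory.
#' @param overwrite Refuse to clobber existing files unless `TRUE`.
#' @return Invisibly, the written file paths.
#' @export
write_outputs <- function(features, qc, out_dir, overwrite = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ft <- file.path(out_dir, "features.tsv")
  qf <- file.path(out_dir, "qc_report.json")
  for (f in c(ft, qf)) {
    if (file.exists(f) && !overwrite) stop("refusing to overwrite ", f)
  }
  utils::write.table(features, ft, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "")
  jsonlite::write_json(qc, qf, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(c(ft, qf))
}

#' Read a feature table written by [write_outputs()]
#'
#' @param path Path to `features.tsv`.
#' @return Tibble with empty cells read back as `NA`.
#' @export
read_feature_table <- function(path) {
  tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                      na.strings = "", stringsAsFactors = FALSE))
}
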