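# Recording-level ingestion: locate the two EEG derivations, map R&K
# hypnogram labels onto the five AASM stages, and cut labelled 30 s epochs.

REQUIRED_CHANNELS <- c("Fpz-Cz", "Pz-Oz")
AASM_STAGES <- c("W", "N1", "N2", "N3", "R")
EPOCH_SECONDS <- 30
EPOCH_SAMPLES <- 3000L

#' Subject metadata
#'
#' Age group boundaries follow the three-tertile cohort convention:
#' young 25-45, middle 46-69, old 70-101 years.
#'
#' @param age age in years.
#' @param sex `"female"` or `"male"`.
#' @return a `subject_meta` list with `age`, `sex` and derived `age_group`.
#' @export
subject_meta <- function(age, sex = c("female", "male")) {
  sex <- match.arg(sex)
  structure(list(age = age, sex = sex, age_group = age_group_of(age)),
            class = "subject_meta")
}

#' @rdname subject_meta
#' @export
age_group_of <- function(age) {
  stopifnot(is.numeric(age), length(age) >= 1)
  out <- ifelse(age >= 25 & age <= 45, "young",
         ifelse(age >= 46 & age <= 69, "middle",
         ifelse(age >= 70 & age <= 101, "old", NA_character_)))
  if (anyNA(out))
    stop("age outside the supported 25-101 year range: ",
         paste(age[is.na(out)], collapse = ", "))
  out
}

#' Read a two-channel sleep EEG recording from EDF
#'
#' Extracts exactly the Fpz-Cz and Pz-Oz derivations (matched
#' case-insensitively as substrings, so exporter variants like
#' `"EEG Fpz-Cz"` resolve) and checks they share one sampling rate.
#'
#' @param path path to an EDF signal file.
#' @param subject_id identifier attached to the recording; defaults to the
#'   file name without extension.
#' @return a `sleep_recording`: list with `subject_id`, `signal` (2 x N
#'   matrix, rows Fpz-Cz then Pz-Oz), `fs` (Hz) and `start_time`.
#' @export
read_recording <- function(path, subject_id = sub("\\.edf$", "", basename(path),
                                                  ignore.case = TRUE)) {
  edf <- read_edf(path)
  labels <- names(edf$signals)
  pick <- function(key) {
    hit <- grep(key, labels, ignore.case = TRUE, fixed = FALSE)
    if (length(hit) == 0)
      stop("required channel '", key, "' not found in ", path,
           " (channels: ", paste(labels, collapse = ", "), ")")
    hit[1]
  }
  idx <- vapply(REQUIRED_CHANNELS, pick, integer(1))
  rates <- edf$sampling_rates[idx]
  if (length(unique(rates)) != 1)
    stop("channels '", paste(labels[idx], collapse = "', '"),
         "' have different sampling rates")
  signal <- do.call(rbind, edf$signals[idx])
  rownames(signal) <- REQUIRED_CHANNELS
  structure(list(subject_id = subject_id, signal = signal,
                 fs = unname(rates[1]),
                 start_time = paste(edf$header$start_date, edf$header$start_time)),
            class = "sleep_recording")
}

#' @export
print.sleep_recording <- function(x, ...) {
  cat(sprintf("<sleep_recording> %s: %d channels x %d samples @ %g Hz (%.1f min)\n",
              x$subject_id, nrow(x$signal), ncol(x$signal), x$fs,
              ncol(x$signal) / x$fs / 60))
  invisible(x)
}

#' Read a hypnogram from an EDF+ annotation file
#'
#' @param path path to an EDF+ file whose annotation channel carries sleep
#'   stage labels.
#' @return data frame with `onset`, `duration` (seconds) and `label`.
#' @export
read_hypnogram <- function(path) {
  edf <- read_edf(path)
  if (is.null(edf$annotations))
    stop("no annotation channel found in ", path)
  edf$annotations
}

#' Map an R&K stage label to an AASM stage
#'
#' The eight R&K scoring categories collapse onto the five AASM stages:
#' stages 3 and 4 merge into N3, while movement time and unscored data are
#' excluded from analysis.
#'
#' @param rk_label character vector of R&K labels. Accepts both full
#'   hypnogram strings (`"Sleep stage W"`, `"Movement time"`) and short
#'   forms (`"W"`, `"1"`..`"4"`, `"R"`, `"Movement"`, `"Unknown"`, `"?"`).
#' @return character vector over `{"W","N1","N2","N3","R","EXCLUDED"}`.
#'   Unrecognized labels are an error, never silently dropped.
#' @export
map_stage_label <- function(rk_label) {
  key <- toupper(trimws(sub("^Sleep stage\\s*", "", rk_label, ignore.case = TRUE)))
  lut <- c("W" = "W", "1" = "N1", "2" = "N2", "3" = "N3", "4" = "N3",
           "R" = "R", "REM" = "R",
           "MOVEMENT" = "EXCLUDED", "MOVEMENT TIME" = "EXCLUDED",
           "UNKNOWN" = "EXCLUDED", "?" = "EXCLUDED")
  out <- lut[key]
  if (anyNA(out))
    stop("unrecognized stage label(s): ",
         paste(unique(rk_label[is.na(out)]), collapse = ", "))
  unname(out)
}

#' Cut a recording into labelled 30 s epochs
#'
#' Tiles each annotated interval into non-overlapping 30 s windows aligned
#' to the annotation onset. Windows whose label maps to `EXCLUDED`
#' (movement, unscored) are dropped, as are partial trailing windows and
#' windows extending past the end of the recording (with a warning).
#'
#' @param recording a `sleep_recording` at 100 Hz.
#' @param annotations hypnogram data frame (`onset`, `duration`, `label`).
#' @param meta a [subject_meta()] attached to every epoch.
#' @param wake_trim_minutes if set, keep only W epochs within this many
#'   minutes of the first/last non-W epoch, discarding long pre/post-sleep
#'   wake stretches; default keeps everything.
#' @return list of `sleep_epoch` objects (`signal` 2 x 3000 matrix, `stage`,
#'   `meta`, `subject_id`, `epoch_index`, `onset`).
#' @export
segment_epochs <- function(recording, annotations, meta,
                           wake_trim_minutes = NULL) {
  stopifnot(inherits(recording, "sleep_recording"),
            inherits(meta, "subject_meta"))
  if (recording$fs != 100)
    stop("expected a 100 Hz recording, got ", recording$fs, " Hz")
  n_total <- ncol(recording$signal)
  rec_seconds <- n_total / recording$fs

  epochs <- list()
  for (i in seq_len(nrow(annotations))) {
    stage <- map_stage_label(annotations$label[i])
    onset <- annotations$onset[i]
    duration <- annotations$duration[i]
    if (onset + duration > rec_seconds) {
      warning("annotation at ", onset, " s extends past end of recording (",
              rec_seconds, " s); truncating")
      duration <- max(0, rec_seconds - onset)
    }
    if (stage == "EXCLUDED") next
    n_win <- floor(duration / EPOCH_SECONDS)
    for (w in seq_len(n_win)) {
      t0 <- onset + (w - 1) * EPOCH_SECONDS
      i0 <- round(t0 * recording$fs) + 1L
      epochs[[length(epochs) + 1L]] <- structure(
        list(signal = recording$signal[, i0:(i0 + EPOCH_SAMPLES - 1L), drop = FALSE],
             stage = stage, meta = meta, subject_id = recording$subject_id,
             epoch_index = length(epochs) + 1L, onset = t0),
        class = "sleep_epoch")
    }
  }

  if (!is.null(wake_trim_minutes) && length(epochs)) {
    stages <- vapply(epochs, `[[`, character(1), "stage")
    onsets <- vapply(epochs, `[[`, numeric(1), "onset")
    sleep_onsets <- onsets[stages != "W"]
    if (length(sleep_onsets)) {
      lo <- min(sleep_onsets) - wake_trim_minutes * 60
      hi <- max(sleep_onsets) + wake_trim_minutes * 60
      keep <- stages != "W" | (onsets >= lo & onsets <= hi)
      epochs <- epochs[keep]
    }
  }
  for (i in seq_along(epochs)) epochs[[i]]$epoch_index <- i
  epochs
}

#' @export
print.sleep_epoch <- function(x, ...) {
  cat(sprintf("<sleep_epoch> %s #%d: stage %s, %d x %d samples (age %g, %s)\n",
              x$subject_id, x$epoch_index, x$stage,
              nrow(x$signal), ncol(x$signal), x$meta$age, x$meta$sex))
  invisible(x)
}

#' Tabulate epochs into a manifest
#'
#' @param epochs list of `sleep_epoch` objects.
#' @return data frame with one row per epoch: `subject_id`, `epoch_index`,
#'   `stage`, `age`, `sex`, `age_group`.
#' @export
epoch_manifest <- function(epochs) {
  data.frame(
    subject_id = vapply(epochs, `[[`, character(1), "subject_id"),
    epoch_index = vapply(epochs, `[[`, integer(1), "epoch_index"),
    stage = vapply(epochs, `[[`, character(1), "stage"),
    age = vapply(epochs, function(e) e$meta$age, numeric(1)),
    sex = vapply(epochs, function(e) e$meta$sex, character(1)),
    age_group = vapply(epochs, function(e) e$meta$age_group, character(1)),
    stringsAsFactors = FALSE)
}
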