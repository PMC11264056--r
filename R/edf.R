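# Minimal European Data Format (EDF / EDF+) reader and writer.
#
# Covers what two-channel polysomnography needs: 16-bit continuous signal
# files and EDF+ annotation channels carrying hypnogram labels as
# time-stamped annotation lists (TALs). EDF+D discontinuous files are not
# supported.

EDF_HEADER_BYTES <- 256L
EDF_SIGNAL_HEADER_BYTES <- 256L
TAL_DUR_SEP <- "\x15"   # separates onset from duration inside a TAL
TAL_TEXT_SEP <- "\x14"  # separates duration from text and text from text

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x, type = "bytes") > width)
    stop("EDF header field too long: '", x, "' (max ", width, " bytes)")
  formatC(x, width = -width)
}

# 8-char ASCII numeric field; EDF allows plain decimal notation only.
num_field <- function(x, width = 8) {
  s <- format(x, trim = TRUE, scientific = FALSE)
  if (nchar(s) > width) s <- substr(format(signif(x, 6), scientific = FALSE), 1, width)
  pad_field(s, width)
}

#' Write signals to an EDF(+) file
#'
#' Writes continuous signals as 16-bit EDF, optionally with an EDF+
#' annotation channel carrying stage labels. Each signal is linearly
#' quantized onto the 16-bit digital range over its own physical range, so
#' the round-trip error is at most half the quantization step
#' `(phys_max - phys_min) / 65535`.
#'
#' @param path output file path.
#' @param signals list of numeric vectors, all the same length.
#' @param labels character vector of channel labels (<= 16 bytes each).
#' @param fs sampling rate in Hz; must divide the signal length so the file
#'   tiles into whole 1 s data records.
#' @param annotations optional data frame with columns `onset`, `duration`
#'   (seconds) and `label`; stored in an EDF+ annotation channel.
#' @param patient_id,recording_id free-text header fields.
#' @param physical_range optional `c(min, max)` applied to every signal;
#'   default is each signal's own symmetric range.
#' @return `path`, invisibly.
#' @seealso [read_edf()], [write_hypnogram_edf()]
#' @export
write_edf <- function(path, signals, labels, fs,
                      annotations = NULL,
                      patient_id = "X X X X", recording_id = "Startdate X X X X",
                      physical_range = NULL) {
  stopifnot(is.list(signals), length(signals) >= 1,
            length(labels) == length(signals))
  n <- unique(vapply(signals, length, integer(1)))
  if (length(n) != 1) stop("all signals must have the same length")
  if (n %% fs != 0)
    stop("signal length (", n, ") must be a whole number of seconds at ", fs, " Hz")
  n_rec <- n %/% fs
  ns <- length(signals)

  tal_bytes <- NULL
  if (!is.null(annotations)) {
    tal_bytes <- build_tal_records(annotations, n_rec)
    ns <- ns + 1L
  }

  dig_min <- -32768; dig_max <- 32767
  ranges <- lapply(signals, function(x) {
    if (!is.null(physical_range)) return(physical_range)
    a <- max(abs(x), 1e-6)
    c(-signif(a * 1.0001, 5), signif(a * 1.0001, 5))
  })

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),
    pad_field(patient_id, 80),
    pad_field(recording_id, 80),
    pad_field("01.01.00", 8),
    pad_field("00.00.00", 8),
    pad_field(EDF_HEADER_BYTES + ns * EDF_SIGNAL_HEADER_BYTES, 8),
    pad_field(if (is.null(annotations)) "" else "EDF+C", 44),
    pad_field(n_rec, 8),
    pad_field(1, 8),
    pad_field(ns, 4))
  writeChar(hdr, con, eos = NULL)

  sig_labels <- labels
  spr <- rep(as.integer(fs), length(signals))
  pmins <- vapply(ranges, `[`, numeric(1), 1)
  pmaxs <- vapply(ranges, `[`, numeric(1), 2)
  dmins <- rep(dig_min, length(signals))
  dmaxs <- rep(dig_max, length(signals))
  dims <- rep("uV", length(signals))
  if (!is.null(annotations)) {
    sig_labels <- c(sig_labels, "EDF Annotations")
    spr <- c(spr, length(tal_bytes[[1]]) %/% 2L)
    pmins <- c(pmins, -1); pmaxs <- c(pmaxs, 1)
    dmins <- c(dmins, dig_min); dmaxs <- c(dmaxs, dig_max)
    dims <- c(dims, "")
  }
  field <- function(vals, width)
    writeChar(paste0(vapply(vals, pad_field, character(1), width = width),
                     collapse = ""), con, eos = NULL)
  field(sig_labels, 16)
  field(rep("", ns), 80)                       # transducer
  field(dims, 8)
  writeChar(paste0(vapply(pmins, num_field, character(1)), collapse = ""), con, eos = NULL)
  writeChar(paste0(vapply(pmaxs, num_field, character(1)), collapse = ""), con, eos = NULL)
  field(dmins, 8)
  field(dmaxs, 8)
  field(rep("", ns), 80)                       # prefiltering
  field(spr, 8)
  field(rep("", ns), 32)                       # reserved

  digital <- mapply(function(x, rg) {
    d <- round((x - rg[1]) / (rg[2] - rg[1]) * (dig_max - dig_min) + dig_min)
    as.integer(pmin(pmax(d, dig_min), dig_max))
  }, signals, ranges, SIMPLIFY = FALSE)

  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (s in seq_along(signals))
      writeBin(digital[[s]][idx], con, size = 2, endian = "little")
    if (!is.null(annotations))
      writeBin(tal_bytes[[r]], con)
  }
  invisible(path)
}

# Build one raw TAL block per data record: record r carries its timekeeping
# TAL plus every annotation whose onset falls in [r-1, r) seconds. All blocks
# are padded with NUL to a common length.
build_tal_records <- function(annotations, n_rec) {
  stopifnot(all(c("onset", "duration", "label") %in% names(annotations)))
  recs <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    t0 <- r - 1
    bytes <- c(charToRaw(sprintf("+%g%s%s", t0, TAL_TEXT_SEP, TAL_TEXT_SEP)), as.raw(0))
    sel <- annotations$onset >= t0 & annotations$onset < r
    for (i in which(sel)) {
      tal <- sprintf("+%g%s%g%s%s%s",
                     annotations$onset[i], TAL_DUR_SEP,
                     annotations$duration[i], TAL_TEXT_SEP,
                     annotations$label[i], TAL_TEXT_SEP)
      bytes <- c(bytes, charToRaw(tal), as.raw(0))
    }
    recs[[r]] <- bytes
  }
  max_len <- max(vapply(recs, length, integer(1)))
  if (max_len %% 2L == 1L) max_len <- max_len + 1L
  lapply(recs, function(b) c(b, raw(max_len - length(b))))
}

read_edf_header <- function(con) {
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  h <- list(version = rd(8), patient_id = rd(80), recording_id = rd(80),
            start_date = rd(8), start_time = rd(8),
            header_bytes = as.integer(rd(8)), reserved = rd(44),
            n_records = as.integer(rd(8)), record_duration = as.numeric(rd(8)),
            n_signals = as.integer(rd(4)))
  ns <- h$n_signals
  sig <- function(w) vapply(seq_len(ns), function(i) trimws(readChar(con, w, useBytes = TRUE)),
                            character(1))
  h$label <- sig(16)
  h$transducer <- sig(80)
  h$dimension <- sig(8)
  h$phys_min <- as.numeric(sig(8))
  h$phys_max <- as.numeric(sig(8))
  h$dig_min <- as.numeric(sig(8))
  h$dig_max <- as.numeric(sig(8))
  h$prefilter <- sig(80)
  h$samples_per_record <- as.integer(sig(8))
  h$sig_reserved <- sig(32)
  h
}

#' Read an EDF(+) file
#'
#' Parses the header, de-quantizes every ordinary signal to physical units,
#' and decodes any "EDF Annotations" channel into an annotation table.
#'
#' @param path EDF file path.
#' @return a list with elements `header` (parsed header fields), `signals`
#'   (named list of numeric vectors, annotation channels excluded),
#'   `sampling_rates` (Hz per signal) and `annotations` (data frame with
#'   `onset`, `duration`, `label`, or `NULL`).
#' @seealso [write_edf()], [read_recording()]
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  h <- read_edf_header(con)
  spr <- h$samples_per_record
  rec_bytes <- sum(spr) * 2L
  data <- readBin(con, "raw", n = rec_bytes * h$n_records)
  if (length(data) < rec_bytes * h$n_records)
    stop("truncated EDF data section in ", path)

  is_annot <- h$label == "EDF Annotations"
  offsets <- c(0L, cumsum(spr * 2L))
  signals <- list(); rates <- numeric(0); annot_raw <- raw(0)
  for (s in seq_len(h$n_signals)) {
    idx <- unlist(lapply(seq_len(h$n_records), function(r) {
      base <- (r - 1L) * rec_bytes + offsets[s]
      (base + 1L):(base + spr[s] * 2L)
    }))
    bytes <- data[idx]
    if (is_annot[s]) { annot_raw <- c(annot_raw, bytes); next }
    dig <- readBin(bytes, "integer", n = length(bytes) %/% 2L,
                   size = 2, signed = TRUE, endian = "little")
    gain <- (h$phys_max[s] - h$phys_min[s]) / (h$dig_max[s] - h$dig_min[s])
    signals[[h$label[s]]] <- h$phys_min[s] + gain * (dig - h$dig_min[s])
    rates <- c(rates, spr[s] / h$record_duration)
  }
  names(rates) <- names(signals)
  annotations <- if (length(annot_raw)) parse_tals(annot_raw) else NULL
  list(header = h, signals = signals, sampling_rates = rates,
       annotations = annotations)
}

# Decode a raw TAL byte stream into onset/duration/label rows. Timekeeping
# TALs (empty annotation text) are dropped. NUL bytes delimit TALs, so they
# are remapped to a sentinel and split on first.
parse_tals <- function(bytes) {
  tal_strings <- Filter(nzchar,
                        strsplit(rawToChar(replace_nul(bytes)), "\x01", fixed = TRUE)[[1]])
  out <- list()
  for (tal in tal_strings) {
    parts <- strsplit(tal, TAL_TEXT_SEP, fixed = TRUE)[[1]]
    if (length(parts) < 2 || !nzchar(parts[2])) next  # timekeeping TAL
    head_part <- strsplit(parts[1], TAL_DUR_SEP, fixed = TRUE)[[1]]
    onset <- as.numeric(head_part[1])
    duration <- if (length(head_part) > 1) as.numeric(head_part[2]) else 0
    for (lab in parts[-1]) {
      if (!nzchar(lab)) next
      out[[length(out) + 1L]] <- data.frame(onset = onset, duration = duration,
                                            label = lab, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  res[order(res$onset), , drop = FALSE]
}

replace_nul <- function(bytes) {
  bytes[bytes == as.raw(0)] <- as.raw(1)
  bytes
}

#' Write a hypnogram as an EDF+ annotation file
#'
#' @param path output file path.
#' @param annotations data frame with `onset`, `duration` (seconds) and
#'   `label` (stage strings such as `"Sleep stage W"`).
#' @param total_duration recording length in seconds; defaults to the end of
#'   the last annotation.
#' @return `path`, invisibly.
#' @export
write_hypnogram_edf <- function(path, annotations,
                                total_duration = max(annotations$onset + annotations$duration)) {
  tal <- paste0("+0", TAL_TEXT_SEP, TAL_TEXT_SEP)
  body <- vapply(seq_len(nrow(annotations)), function(i)
    sprintf("+%g%s%g%s%s%s", annotations$onset[i], TAL_DUR_SEP,
            annotations$duration[i], TAL_TEXT_SEP,
            annotations$label[i], TAL_TEXT_SEP), character(1))
  payload <- c(charToRaw(tal), as.raw(0),
               unlist(lapply(body, function(b) c(charToRaw(b), as.raw(0)))))
  if (length(payload) %% 2L == 1L) payload <- c(payload, raw(1))
  spr <- length(payload) %/% 2L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8), pad_field("X X X X", 80),
    pad_field("Startdate X X X X", 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(EDF_HEADER_BYTES + EDF_SIGNAL_HEADER_BYTES, 8),
    pad_field("EDF+C", 44),
    pad_field(1, 8),
    pad_field(format(total_duration, scientific = FALSE), 8),
    pad_field(1, 4))
  writeChar(hdr, con, eos = NULL)
  writeChar(pad_field("EDF Annotations", 16), con, eos = NULL)
  writeChar(pad_field("", 80), con, eos = NULL)
  writeChar(pad_field("", 8), con, eos = NULL)
  writeChar(num_field(-1), con, eos = NULL)
  writeChar(num_field(1), con, eos = NULL)
  writeChar(pad_field(-32768, 8), con, eos = NULL)
  writeChar(pad_field(32767, 8), con, eos = NULL)
  writeChar(pad_field("", 80), con, eos = NULL)
  writeChar(pad_field(spr, 8), con, eos = NULL)
  writeChar(pad_field("", 32), con, eos = NULL)
  writeBin(payload, con)
  invisible(path)
}
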