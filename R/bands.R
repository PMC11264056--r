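# Rhythm-band decomposition: zero-phase Butterworth band-pass filtering of
# 30 s epochs into the six sleep rhythm bands.

#' The six-band sleep rhythm scheme
#'
#' Delta 0.5-4, theta 4-8, alpha 8-13, beta 13-30, sleep spindle 11-16 and
#' sawtooth 3-7 Hz. The spindle band deliberately overlaps alpha/beta and
#' the sawtooth band overlaps delta/theta; no orthogonalization is applied.
#'
#' @param bands optional named list of `c(low, high)` pairs in Hz to
#'   override or replace the defaults; edges must satisfy 0 < low < high
#'   < 50 (Nyquist at 100 Hz).
#' @return a `band_scheme` data frame with columns `band`, `low`, `high`.
#' @export
band_scheme <- function(bands = NULL) {
  default <- list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13),
                  beta = c(13, 30), spindle = c(11, 16), sawtooth = c(3, 7))
  if (!is.null(bands)) {
    stopifnot(is.list(bands), !is.null(names(bands)))
    default[names(bands)] <- bands
  }
  lows <- vapply(default, `[`, numeric(1), 1)
  highs <- vapply(default, `[`, numeric(1), 2)
  if (any(lows <= 0) || any(highs >= 50) || any(lows >= highs))
    stop("band edges must satisfy 0 < low < high < 50 Hz")
  structure(data.frame(band = names(default), low = unname(lows),
                       high = unname(highs), stringsAsFactors = FALSE),
            class = c("band_scheme", "data.frame"))
}

# Filter designs are pure functions of (order, edges, fs); cache them, the
# polynomial design work dominates short-epoch filtering otherwise.
.filter_cache <- new.env(parent = emptyenv())

butter_design <- function(order, low, high, fs) {
  key <- paste(order, low, high, fs, sep = "|")
  flt <- .filter_cache[[key]]
  if (is.null(flt)) {
    flt <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
    .filter_cache[[key]] <- flt
  }
  flt
}

# Direct-form IIR via stats::filter: FIR numerator by one-sided convolution,
# AR denominator by recursion. Identical output to the reference difference
# equation, C-level throughout.
iir_filter <- function(b, a, x) {
  nb <- length(b)
  v <- stats::filter(c(rep(0, nb - 1L), x), b, method = "convolution", sides = 1)
  v <- v[-seq_len(nb - 1L)]
  as.numeric(stats::filter(v / a[1], -a[-1] / a[1], method = "recursive"))
}

# Zero-phase band-pass: 4th-order Butterworth run forward then backward
# (effective 8th order, zero phase). Reflection padding of 300 samples
# absorbs filter transients at the epoch edges.
butter_bandpass <- function(x, low, high, fs, order = 4, pad = 300) {
  flt <- butter_design(order, low, high, fs)
  n <- length(x)
  pad <- min(pad, n - 1L)
  xp <- c(rev(x[2:(pad + 1L)]), x, rev(x[(n - pad):(n - 1L)]))
  y <- iir_filter(flt$b, flt$a, xp)
  y <- rev(iir_filter(flt$b, flt$a, rev(y)))
  as.numeric(y[(pad + 1L):(pad + n)])
}

apply_bandpass <- function(epoch, low, high) {
  out <- epoch
  for (ch in seq_len(nrow(epoch$signal)))
    out$signal[ch, ] <- butter_bandpass(epoch$signal[ch, ], low, high, fs = 100)
  out
}

#' Broadband 0.5-30 Hz filtering of an epoch
#'
#' The standard broadband pass applied before rhythm extraction.
#'
#' @param epoch a `sleep_epoch` (2 x 3000 at 100 Hz).
#' @return the epoch with each channel band-passed 0.5-30 Hz, zero phase.
#' @export
broadband_filter <- function(epoch) {
  stopifnot(inherits(epoch, "sleep_epoch"))
  apply_bandpass(epoch, 0.5, 30)
}

#' Extract one rhythm band from an epoch
#'
#' @param epoch a `sleep_epoch`.
#' @param band band name present in `scheme`.
#' @param scheme a [band_scheme()].
#' @return a `band_epoch`: the epoch with both channels band-passed to the
#'   band's interval, plus a `band` element.
#' @export
extract_band <- function(epoch, band, scheme = band_scheme()) {
  stopifnot(inherits(epoch, "sleep_epoch"))
  row <- scheme[scheme$band == band, ]
  if (nrow(row) != 1) stop("unknown band: ", band)
  out <- apply_bandpass(epoch, row$low, row$high)
  out$band <- band
  class(out) <- c("band_epoch", class(out))
  out
}
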