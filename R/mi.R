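# Histogram mutual information between the two EEG derivations, per rhythm
# band: I(X;Y) = sum_xy p(x,y) log2[ p(x,y) / (p(x) p(y)) ], estimated from
# an equal-width 2-D histogram. MI is non-negative, symmetric, and zero iff
# the binned variables are independent.

#' Joint histogram of two sequences
#'
#' Discretizes `x` and `y` each into `n_bins` equal-width bins spanning
#' their own `[min, max]` and tabulates the normalized joint distribution.
#'
#' @param x,y numeric sequences of equal length.
#' @param n_bins bins per axis (>= 2).
#' @return list with `joint` (n_bins x n_bins probability matrix summing to
#'   1), `px`, `py` (marginals) and the two `breaks` vectors.
#' @export
joint_histogram <- function(x, y, n_bins = 32) {
  stopifnot(length(x) == length(y), n_bins >= 2)
  bin <- function(v) {
    br <- seq(min(v), max(v), length.out = n_bins + 1L)
    list(idx = pmin(findInterval(v, br, rightmost.closed = TRUE), n_bins),
         breaks = br)
  }
  bx <- bin(x); by <- bin(y)
  joint <- matrix(tabulate((by$idx - 1L) * n_bins + bx$idx, n_bins * n_bins),
                  nrow = n_bins) / length(x)
  dimnames(joint) <- list(seq_len(n_bins), seq_len(n_bins))
  list(joint = joint, px = rowSums(joint), py = colSums(joint),
       breaks_x = bx$breaks, breaks_y = by$breaks)
}

#' Histogram mutual information in bits
#'
#' Equal-width binning of each sequence over its own range, then direct
#' summation of `p(x,y) log2[p(x,y)/(p(x)p(y))]` over the non-zero cells of
#' the joint histogram. The result lies in `[0, log2(n_bins)]`. The optional
#' Miller-Madow correction subtracts the first-order positive bias
#' `(B_x - 1)(B_y - 1 ) / (2 N ln 2)` (occupied-bin counts) for sensitivity
#' checks; the default is the uncorrected plug-in estimate.
#'
#' @param x,y numeric sequences of equal length (>= 2 values).
#' @param n_bins bins per axis; 32 by default (see the methods vignette for
#'   the bias/resolution trade-off behind this choice).
#' @param correction `"none"` (default) or `"miller-madow"`.
#' @return mutual information in bits (scalar, >= 0). Constant input has
#'   zero range and no information: MI is defined as 0 with a warning.
#' @examples
#' x <- rnorm(3000)
#' estimate_mi(x, x, n_bins = 8)           # = entropy of binned x
#' estimate_mi(x, rnorm(3000), n_bins = 8) # near 0
#' @export
estimate_mi <- function(x, y, n_bins = 32, correction = c("none", "miller-madow")) {
  correction <- match.arg(correction)
  if (length(x) != length(y))
    stop("x and y must have equal length (", length(x), " vs ", length(y), ")")
  if (diff(range(x)) == 0 || diff(range(y)) == 0) {
    warning("constant input: mutual information defined as 0")
    return(0)
  }
  h <- joint_histogram(x, y, n_bins)
  nz <- h$joint > 0
  ratio <- h$joint / outer(h$px, h$py)
  mi <- sum(h$joint[nz] * log2(ratio[nz]))
  if (correction == "miller-madow") {
    bx <- sum(h$px > 0); by <- sum(h$py > 0); bxy <- sum(nz)
    # plug-in I = H(X)+H(Y)-H(X,Y); Miller-Madow adds (B-1)/(2N ln 2) bits
    # to each entropy term, which nets out to a downward MI correction
    mi <- mi + ((bx - 1) + (by - 1) - (bxy - 1)) / (2 * length(x) * log(2))
  }
  max(mi, 0)
}

#' Per-band connectivity of one epoch
#'
#' For each band in the scheme, band-pass both channels and estimate the
#' mutual information between them. A failure in one band (e.g. a constant
#' filtered signal) yields MI 0 for that band without aborting the rest.
#'
#' @param epoch a `sleep_epoch`.
#' @param scheme a [band_scheme()].
#' @param n_bins histogram bins per axis.
#' @param correction passed to [estimate_mi()].
#' @return a `connectivity_vector`: named numeric of six MI values (bits)
#'   with the epoch's `stage` and `meta` attached as attributes.
#' @export
epoch_connectivity <- function(epoch, scheme = band_scheme(), n_bins = 32,
                               correction = "none") {
  stopifnot(inherits(epoch, "sleep_epoch"))
  mi <- vapply(seq_len(nrow(scheme)), function(b) {
    be <- extract_band(epoch, scheme$band[b], scheme)
    tryCatch(estimate_mi(be$signal[1, ], be$signal[2, ], n_bins, correction),
             error = function(e) {
               warning("band ", scheme$band[b], ": ", conditionMessage(e),
                       "; MI set to 0")
               0
             })
  }, numeric(1))
  names(mi) <- scheme$band
  structure(mi, stage = epoch$stage, meta = epoch$meta,
            subject_id = epoch$subject_id,
            class = c("connectivity_vector", "numeric"))
}

#' @export
print.connectivity_vector <- function(x, ...) {
  cat(sprintf("<connectivity_vector> stage %s (%s): MI in bits\n",
              attr(x, "stage"), attr(x, "subject_id")))
  print(round(setNames(as.numeric(x), names(x)), 4))
  invisible(x)
}

#' Connectivity feature table for a set of epochs
#'
#' The feature matrix feeding both the group statistics and the staging
#' experiment: one row per epoch (default) or per subject x stage
#' (`aggregate = "subject"`, MI computed on the concatenated band signals
#' of all the subject's epochs of that stage — longer samples, lower
#' estimator variance).
#'
#' @param epochs list of `sleep_epoch` objects, or a `sleep_cohort`.
#' @param scheme a [band_scheme()].
#' @param n_bins histogram bins per axis.
#' @param aggregate `"epoch"` or `"subject"`.
#' @param correction passed to [estimate_mi()].
#' @return a `conn_features` data frame: `subject_id`, `stage`, `age`,
#'   `sex`, `age_group`, then `mi_delta` ... `mi_sawtooth`.
#' @export
connectivity_features <- function(epochs, scheme = band_scheme(), n_bins = 32,
                                  aggregate = c("epoch", "subject"),
                                  correction = "none") {
  aggregate <- match.arg(aggregate)
  if (inherits(epochs, "sleep_cohort")) epochs <- epochs$epochs
  stopifnot(length(epochs) >= 1)
  mi_cols <- paste0("mi_", scheme$band)

  if (aggregate == "epoch") {
    rows <- lapply(epochs, function(e) {
      mi <- epoch_connectivity(e, scheme, n_bins, correction)
      cbind(data.frame(subject_id = e$subject_id, stage = e$stage,
                       age = e$meta$age, sex = e$meta$sex,
                       age_group = e$meta$age_group, stringsAsFactors = FALSE),
            as.data.frame(as.list(setNames(as.numeric(mi), mi_cols))))
    })
  } else {
    key <- paste(vapply(epochs, `[[`, character(1), "subject_id"),
                 vapply(epochs, `[[`, character(1), "stage"), sep = "\r")
    rows <- lapply(split(epochs, key), function(grp) {
      e1 <- grp[[1]]
      mi <- vapply(seq_len(nrow(scheme)), function(b) {
        bands <- lapply(grp, extract_band, band = scheme$band[b], scheme = scheme)
        x <- unlist(lapply(bands, function(be) be$signal[1, ]))
        y <- unlist(lapply(bands, function(be) be$signal[2, ]))
        estimate_mi(x, y, n_bins, correction)
      }, numeric(1))
      cbind(data.frame(subject_id = e1$subject_id, stage = e1$stage,
                       age = e1$meta$age, sex = e1$meta$sex,
                       age_group = e1$meta$age_group, stringsAsFactors = FALSE),
            as.data.frame(as.list(setNames(mi, mi_cols))))
    })
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("conn_features", "data.frame")
  out
}

mi_columns <- function(features) grep("^mi_", names(features), value = TRUE)
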