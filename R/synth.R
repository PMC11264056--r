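# Synthetic two-channel sleep EEG: sums of band-limited Gaussian noise with
# controllable cross-channel coupling per rhythm band. Mixing a shared
# band-limited source into both channels with coefficient rho gives the pair
# a closed-form mutual information of -1/2 * log2(1 - rho^2) bits, which is
# the package's parameter-recovery oracle.

STAGE_LEVELS <- c("W", "N1", "N2", "N3", "R")
AGE_LEVELS <- c("young", "middle", "old")
SEX_LEVELS <- c("female", "male")
HIGH_BANDS <- c("alpha", "beta", "spindle")  # bands at/above 8 Hz

#' Coupling table for the synthetic generator
#'
#' A 4-way array of mixing coefficients rho in [0, 1), indexed by band x
#' stage x age group x sex, controlling the cross-channel coupling of each
#' rhythm band. The defaults are illustrative, not measured values: delta
#' and beta coupling rise monotonically from W to N3, coupling in the bands
#' at or above 8 Hz (alpha, beta, spindle) is higher in females, and
#' spindle-band coupling is higher in the young than in the old.
#'
#' @param base optional band x stage matrix of baseline rho values
#'   (rownames = bands, colnames = stages) replacing the default profile.
#' @param sex_shift added to female cells of the high bands (alpha, beta,
#'   spindle); set 0 for a null cohort.
#' @param age_shift added to young spindle/beta cells and subtracted from
#'   old spindle cells; set 0 for a null cohort.
#' @return a `coupling_table` array with dimensions band(6) x stage(5) x
#'   age_group(3) x sex(2), all cells clamped to [0, 0.98].
#' @export
coupling_table <- function(base = NULL, sex_shift = 0.10, age_shift = 0.10) {
  scheme <- band_scheme()
  if (is.null(base)) {
    base <- rbind(
      delta    = c(W = 0.15, N1 = 0.30, N2 = 0.45, N3 = 0.60, R = 0.25),
      theta    = c(W = 0.15, N1 = 0.30, N2 = 0.35, N3 = 0.35, R = 0.30),
      alpha    = c(W = 0.20, N1 = 0.30, N2 = 0.30, N3 = 0.30, R = 0.30),
      beta     = c(W = 0.15, N1 = 0.30, N2 = 0.45, N3 = 0.60, R = 0.25),
      spindle  = c(W = 0.15, N1 = 0.30, N2 = 0.45, N3 = 0.45, R = 0.30),
      sawtooth = c(W = 0.15, N1 = 0.35, N2 = 0.35, N3 = 0.35, R = 0.40))
  }
  stopifnot(identical(rownames(base), scheme$band),
            identical(colnames(base), STAGE_LEVELS))
  tab <- array(0, dim = c(6, 5, 3, 2),
               dimnames = list(band = scheme$band, stage = STAGE_LEVELS,
                               age_group = AGE_LEVELS, sex = SEX_LEVELS))
  for (a in AGE_LEVELS) for (s in SEX_LEVELS) tab[, , a, s] <- base
  tab[HIGH_BANDS, , , "female"] <- tab[HIGH_BANDS, , , "female"] + sex_shift
  tab["spindle", , "young", ] <- tab["spindle", , "young", ] + age_shift
  tab["beta", , "young", ] <- tab["beta", , "young", ] + age_shift / 2
  tab["spindle", , "old", ] <- tab["spindle", , "old", ] - age_shift / 2
  tab <- pmin(pmax(tab, 0), 0.98)
  structure(tab, class = c("coupling_table", "array"))
}

#' A coupled pair of band-limited Gaussian noise signals
#'
#' Channel 1 is band-limited unit-variance Gaussian noise s; channel 2 is
#' `rho * s + sqrt(1 - rho^2) * u` with u an independent band-limited noise,
#' so the pair has per-sample correlation `rho` and mutual information
#' `-0.5 * log2(1 - rho^2)` bits.
#'
#' @param n number of samples.
#' @param low,high band edges in Hz.
#' @param rho mixing coefficient in [0, 1).
#' @param fs sampling rate in Hz.
#' @param seed optional integer seed (local RNG, session RNG untouched).
#' @return a 2 x n matrix.
#' @export
coupled_band_noise <- function(n, low, high, rho, fs = 100, seed = NULL) {
  stopifnot(rho >= 0, rho < 1)
  with_seed(seed, {
    unitize <- function(x) x / max(sd(x), 1e-12)
    s <- unitize(butter_bandpass(rnorm(n), low, high, fs))
    u <- unitize(butter_bandpass(rnorm(n), low, high, fs))
    rbind(s, rho * s + sqrt(1 - rho^2) * u)
  })
}

#' Generate one synthetic 30 s epoch
#'
#' Each channel is the sum over the six rhythm bands of unit-variance
#' band-limited Gaussian noise; channel 2 shares a fraction `rho_b` of each
#' band's source with channel 1 per the coupling table. Band powers are
#' equal across stages and groups, so group differences are carried by the
#' coupling alone.
#'
#' @param stage one of W, N1, N2, N3, R.
#' @param meta a [subject_meta()].
#' @param coupling a [coupling_table()].
#' @param seed optional integer seed; the same seed reproduces the epoch
#'   exactly.
#' @param subject_id identifier stored on the epoch.
#' @param scheme a [band_scheme()].
#' @return a `sleep_epoch` (2 x 3000 signal at 100 Hz).
#' @export
generate_epoch <- function(stage, meta, coupling = coupling_table(),
                           seed = NULL, subject_id = "synthetic",
                           scheme = band_scheme()) {
  stage <- match.arg(stage, STAGE_LEVELS)
  stopifnot(inherits(meta, "subject_meta"))
  with_seed(seed, {
    ch1 <- numeric(EPOCH_SAMPLES)
    ch2 <- numeric(EPOCH_SAMPLES)
    for (b in seq_len(nrow(scheme))) {
      rho <- coupling[scheme$band[b], stage, meta$age_group, meta$sex]
      pair <- coupled_band_noise(EPOCH_SAMPLES, scheme$low[b], scheme$high[b],
                                 rho, fs = 100)
      ch1 <- ch1 + pair[1, ]
      ch2 <- ch2 + pair[2, ]
    }
    signal <- rbind(ch1, ch2)
    rownames(signal) <- REQUIRED_CHANNELS
    structure(list(signal = signal, stage = stage, meta = meta,
                   subject_id = subject_id, epoch_index = NA_integer_,
                   onset = NA_real_),
              class = "sleep_epoch")
  })
}

#' Cohort specification for the synthetic generator
#'
#' @param n_subjects subjects per (age group x sex) cell (6 cells).
#' @param epochs_per_stage epochs per stage per subject.
#' @param noise_sd standard deviation of white measurement noise added to
#'   both channels (0 disables it).
#' @param seed root seed; fully determines the cohort.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects = 2, epochs_per_stage = 5,
                        noise_sd = 0, seed = 1) {
  stopifnot(n_subjects >= 1, epochs_per_stage >= 1, noise_sd >= 0)
  structure(list(n_subjects = n_subjects, epochs_per_stage = epochs_per_stage,
                 fs = 100, epoch_seconds = EPOCH_SECONDS,
                 noise_sd = noise_sd, seed = seed),
            class = "cohort_spec")
}

#' Generate a balanced synthetic cohort
#'
#' One subject cell per (age group x sex) combination; ages are drawn
#' uniformly within each group's range (young 25-45, middle 46-69, old
#' 70-101). Every subject contributes `epochs_per_stage` epochs of each of
#' the five stages, so the cohort is balanced by construction.
#'
#' @param spec a [cohort_spec()].
#' @param coupling a [coupling_table()].
#' @return a `sleep_cohort`: list with `epochs` (list of `sleep_epoch`) and
#'   `manifest` (one row per epoch, see [epoch_manifest()]).
#' @export
generate_cohort <- function(spec = cohort_spec(), coupling = coupling_table()) {
  stopifnot(inherits(spec, "cohort_spec"))
  age_range <- list(young = c(25, 45), middle = c(46, 69), old = c(70, 101))
  epochs <- list()
  subj_counter <- 0L
  for (a in AGE_LEVELS) for (s in SEX_LEVELS) {
    for (k in seq_len(spec$n_subjects)) {
      subj_counter <- subj_counter + 1L
      sid <- sprintf("S%03d-%s-%s", subj_counter, a, s)
      subj_seed <- child_seed(spec$seed, subj_counter)
      age <- with_seed(subj_seed,
                       round(runif(1, age_range[[a]][1], age_range[[a]][2])))
      meta <- subject_meta(age, s)
      ep_counter <- 0L
      for (st in STAGE_LEVELS) for (e in seq_len(spec$epochs_per_stage)) {
        ep_counter <- ep_counter + 1L
        ep <- generate_epoch(st, meta, coupling,
                             seed = child_seed(subj_seed, ep_counter),
                             subject_id = sid)
        if (spec$noise_sd > 0)
          ep$signal <- ep$signal +
            with_seed(child_seed(subj_seed, 10000L + ep_counter),
                      matrix(rnorm(length(ep$signal), sd = spec$noise_sd),
                             nrow = nrow(ep$signal)))
        ep$epoch_index <- ep_counter
        epochs[[length(epochs) + 1L]] <- ep
      }
    }
  }
  structure(list(epochs = epochs, manifest = epoch_manifest(epochs),
                 spec = spec),
            class = "sleep_cohort")
}

#' @export
print.sleep_cohort <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<sleep_cohort> %d epochs, %d subjects, stages: %s\n",
              nrow(m), length(unique(m$subject_id)),
              paste(names(table(m$stage)), table(m$stage),
                    sep = "=", collapse = " ")))
  invisible(x)
}

#' Write a synthetic cohort as EDF signal + hypnogram pairs
#'
#' Each subject's epochs are concatenated (stage blocks in manifest order)
#' into one `<subject>-PSG.edf` two-channel signal file plus a
#' `<subject>-Hypnogram.edf` EDF+ annotation file with 30 s stage labels,
#' mirroring the pairing convention of public polysomnography archives. A
#' `metadata.csv` with subject age and sex is written alongside.
#'
#' @param cohort a `sleep_cohort`.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_cohort_edf <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sleep_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rk_of <- c(W = "Sleep stage W", N1 = "Sleep stage 1", N2 = "Sleep stage 2",
             N3 = "Sleep stage 3", R = "Sleep stage R")
  meta_rows <- list()
  for (sid in unique(cohort$manifest$subject_id)) {
    eps <- Filter(function(e) e$subject_id == sid, cohort$epochs)
    sig1 <- unlist(lapply(eps, function(e) e$signal[1, ]))
    sig2 <- unlist(lapply(eps, function(e) e$signal[2, ]))
    ann <- data.frame(
      onset = (seq_along(eps) - 1) * EPOCH_SECONDS,
      duration = EPOCH_SECONDS,
      label = unname(rk_of[vapply(eps, `[[`, character(1), "stage")]),
      stringsAsFactors = FALSE)
    write_edf(file.path(dir, paste0(sid, "-PSG.edf")),
              list(sig1, sig2),
              labels = c("EEG Fpz-Cz", "EEG Pz-Oz"), fs = 100,
              patient_id = sid)
    write_hypnogram_edf(file.path(dir, paste0(sid, "-Hypnogram.edf")), ann)
    meta_rows[[sid]] <- data.frame(subject_id = sid, age = eps[[1]]$meta$age,
                                   sex = eps[[1]]$meta$sex,
                                   stringsAsFactors = FALSE)
  }
  write.csv(do.call(rbind, meta_rows), file.path(dir, "metadata.csv"),
            row.names = FALSE)
  invisible(dir)
}
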