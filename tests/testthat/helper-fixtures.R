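# Shared fixtures and independent oracles. The oracles deliberately use
# different primitives (cut/nested loops, explicit sums of squares) from the
# package code paths they check.

toy_epoch <- function(signal, stage = "W", age = 30, sex = "female",
                      subject_id = "T") {
  rownames(signal) <- c("Fpz-Cz", "Pz-Oz")
  structure(list(signal = signal, stage = stage,
                 meta = subject_meta(age, sex), subject_id = subject_id,
                 epoch_index = 1L, onset = 0),
            class = "sleep_epoch")
}

sine_epoch <- function(freq, fs = 100, n = 3000, amplitude = 1) {
  t <- (seq_len(n) - 1) / fs
  s <- amplitude * sin(2 * pi * freq * t)
  toy_epoch(rbind(s, s))
}

# Direct double summation of p(x,y) log2[p(x,y)/(p(x)p(y))] over the cells
# of a count table.
bruteforce_mi_from_counts <- function(counts) {
  p <- counts / sum(counts)
  px <- rowSums(p); py <- colSums(p)
  mi <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p)))
    if (p[i, j] > 0) mi <- mi + p[i, j] * log2(p[i, j] / (px[i] * py[j]))
  mi
}

# Expand a count table into paired integer samples (row value, col value).
counts_to_samples <- function(counts) {
  xs <- ys <- integer(0)
  for (i in seq_len(nrow(counts))) for (j in seq_len(ncol(counts))) {
    k <- counts[i, j]
    if (k > 0) { xs <- c(xs, rep(i, k)); ys <- c(ys, rep(j, k)) }
  }
  list(x = xs, y = ys)
}

# Explicit between/within sums-of-squares decomposition.
bruteforce_anova_F <- function(groups) {
  y <- unlist(groups); n <- length(y); k <- length(groups)
  grand <- mean(y)
  ss_between <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2,
                           numeric(1)))
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  (ss_between / (k - 1)) / (ss_within / (n - k))
}

# Amplitude of the frequency-f component of x (single-bin Fourier
# projection), used to read filter magnitude responses off test sinusoids.
sine_amplitude <- function(x, freq, fs = 100) {
  t <- (seq_along(x) - 1) / fs
  2 * abs(mean(x * exp(-2i * pi * freq * t)))
}

# Small feature table with perfectly stage-separable values (disjoint value
# ranges per stage) in the delta band and uninformative constants elsewhere.
separable_features <- function(n_per_stage = 20, seed = 1) {
  stages <- rep(c("W", "N1", "N2", "N3", "R"), each = n_per_stage)
  centers <- setNames(seq(0, 4), c("W", "N1", "N2", "N3", "R"))
  set.seed(seed)
  data.frame(subject_id = "S", stage = stages, age = 30, sex = "female",
             age_group = "young",
             mi_delta = centers[stages] + runif(length(stages), 0, 0.4),
             mi_theta = 0.1, mi_alpha = 0.1, mi_beta = 0.1,
             mi_spindle = 0.1, mi_sawtooth = 0.1,
             stringsAsFactors = FALSE)
}
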