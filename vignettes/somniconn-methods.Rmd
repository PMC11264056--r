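---
title: "Methods: band-wise EEG connectivity, group statistics and staging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: band-wise EEG connectivity, group statistics and staging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the methodological content of `somniconn`: the model
behind each stage of the pipeline, the parameters that matter and why their
defaults are what they are, what the synthetic generator does and does not
emulate, and the numerical decisions taken where the methodology was
genuinely open.

## The analysis model

The unit of analysis is a 30 s, two-channel (Fpz-Cz, Pz-Oz), 100 Hz EEG
epoch carrying one of the five AASM stage labels (W, N1, N2, N3, R) plus
subject age and sex. Hypnograms scored under the older R&K convention are
mapped on ingestion: stages 3 and 4 merge into N3; movement time and
unscored epochs are excluded outright rather than silently re-labelled.
Age groups use fixed tertile boundaries — young 25–45, middle 46–69, old
70–101 years — so that group membership is a pure function of age.

Each epoch is decomposed into six rhythm bands (delta 0.5–4, theta 4–8,
alpha 8–13, beta 13–30, spindle 11–16, sawtooth 3–7 Hz). The spindle band
overlaps alpha/beta and the sawtooth band overlaps delta/theta; the bands
are used exactly as defined, with no orthogonalization, because the band
scheme is part of the analysis definition, not a free design dimension.

Functional connectivity within a band is the mutual information between
the two band-filtered channels,

$$I(X;Y) = \sum_{x}\sum_{y} p(x,y)\,\log_2\frac{p(x,y)}{p(x)\,p(y)},$$

estimated by the histogram plug-in: each channel is discretized into
`n_bins` equal-width bins spanning its own observed range, and the sum runs
over the non-zero cells of the joint histogram. MI is reported in bits
(base-2 logarithm; the definition leaves the base free, and bits are the
convention this package fixes). The estimator is symmetric by
construction, clamped at zero against floating-point undershoot, and
bounded by `log2(n_bins)`.

## Tunable parameters

* **`n_bins` (histogram bins per axis, default 32).** The plug-in
  estimator trades a positive small-sample bias (roughly
  `(B−1)²/(2N ln 2)` bits for B occupied bins and N samples) against a
  negative discretization loss that grows with the underlying dependence.
  At the package's reference operating point for parameter recovery —
  30 000-sample Gaussian pairs with mixing up to ρ = 0.9 — 16 bins loses
  ≈ 0.12 bits to discretization at ρ = 0.9, while 32 bins keeps both error
  terms within a few hundredths of a bit (the acceptance suite measures
  this directly). 32 is therefore the default; the parameter remains
  exposed, and a Miller–Madow-corrected variant
  (`correction = "miller-madow"`) is available for sensitivity checks.
  Per-epoch MI (N = 3000) carries a larger, nearly uniform positive bias;
  since every group comparison is between MI values computed at identical
  N and `n_bins`, this bias cancels in the contrasts the pipeline reports.
* **Filter order (4) and padding (reflection, 300 samples).** Band-pass
  filters are 4th-order Butterworth run forward-backward, giving an
  effective 8th-order magnitude response with exactly zero phase —
  standard EEG practice, stable at a 0.5 Hz lower edge on 100 Hz data.
  Filtering is per 30 s epoch; 3 s of mirrored samples on each side absorb
  the filter transient. The contract (pass-band gain within 5%, stop-band
  attenuation ≥ 20 dB, zero lag) is asserted per band in the tests.
* **Aggregation level (`aggregate = "epoch"` or `"subject"`).** Whether
  the statistical unit of the group comparisons is the epoch or the
  subject × stage mean is a genuine open choice for this kind of analysis.
  Both are implemented: the default computes MI per epoch; the subject
  mode concatenates all of a subject's band signals per stage before
  estimating MI (longer samples, lower estimator variance, subjects as
  independent units). Neither is asserted as canonical.
* **Post-hoc method (`"bonferroni"` default, `"tukey"` optional).**
  The procedure is deliberately gated: pairwise comparisons are only
  admissible after a significant omnibus ANOVA (calling them otherwise is
  an error). Bonferroni-adjusted Welch pairwise t tests are the default —
  conservative, robust to the unequal group sizes age/sex cells produce,
  and correcting within each omnibus family only (the scope is recorded in
  the output metadata). Tukey HSD on the pooled fit is the alternative.
* **Classifier operating points.** KNN uses k = 9 and the random forest 50
  trees; the SVM uses an RBF kernel with library-default cost and gamma.
  Features are z-scored with training-fold statistics for the
  distance-based and margin-based classifiers (essential; the forest is
  scale-invariant and takes raw features). The 70/30 split is at the epoch
  level — the literal reading of "randomly divide the dataset" — which
  leaks subject identity across folds; a subject-level split would be the
  stricter design and the epoch-level default should be kept in mind when
  interpreting absolute accuracies.
* **Class balancing.** Stage counts are equalized to the minority stage by
  seeded random deletion, re-drawn inside every round (seed + round index)
  so rounds differ in both balance and split. Metrics are macro-averaged
  one-vs-rest over the five stages; overall accuracy is the confusion
  matrix trace over the total, which the tests pin to the one-vs-rest
  accounting. A class never predicted contributes precision 0 rather than
  NaN. Output tables name the metrics precision/recall; sensitivity is
  recall under another name, and specificity is not reported.

## The synthetic generator

`generate_epoch()` builds channel 1 as a sum over the six bands of
unit-variance band-limited Gaussian noise, and channel 2 as
`ρ_b · s_b + sqrt(1 − ρ_b²) · u_b` per band with independent `u_b`, where
`ρ_b` comes from a band × stage × age-group × sex coupling table. Mixing
correlated Gaussians this way gives each band pair the closed-form mutual
information `−½ log2(1 − ρ²)` bits — the parameter-recovery oracle the
test suite and acceptance script check against. Band powers are held equal
across stages and groups, so any group difference is carried by coupling
alone, which is exactly what the MI analysis measures.

The default coupling table is illustrative, not fitted to any recording:
delta and beta coupling rise monotonically W → N3, the bands at/above 8 Hz
(alpha, beta, spindle) couple 0.10 higher in females, and spindle coupling
is higher in the young and lower in the old. These defaults inject the
qualitative structure the group analysis is designed to detect; a null
cohort (flat table, zero shifts) is used to verify the pipeline does not
manufacture effects.

What the generator does **not** emulate: oscillatory bursts (real
spindles, K-complexes), arousals, artifacts (eye blinks, EMG), 1/f
spectral slope, age-dependent slowing of band power, or inter-epoch
dependence within a night. Passing tests therefore demonstrate estimator
and pipeline correctness under a stationary Gaussian band-mixture model —
they do not certify effect sizes or accuracies on clinical recordings.

Cohorts write out as standard EDF signal/hypnogram pairs (16-bit physical
quantization, EDF+ time-stamped annotation lists), so the synthetic path
also exercises the full ingestion code; the round-trip is tested to the
quantization step and cross-checked against an independent EDF reader.

## Numerical and degenerate-case decisions

* Constant (zero-range) input to the MI estimator is defined as MI = 0
  with a warning, never NaN; a failing band inside `epoch_connectivity()`
  yields 0 for that band without aborting the others.
* Histogram binning uses half-open bins with the top edge closed, so the
  maximum lands in the last bin and every sample is counted exactly once.
* ANOVA rejects groups with fewer than two values and zero total variance
  explicitly; identical groups give F = 0, p = 1.
* Epoch windows are half-open `[onset, onset + 30 s)`, 0-based seconds,
  aligned to annotation onsets (sleep-archive hypnograms are already 30 s
  aligned; no re-alignment heuristic). Partial trailing windows are
  dropped; annotations running past the recording end are truncated with a
  warning. Optional `wake_trim_minutes` keeps only wake epochs within a
  window of the first/last sleep epoch, since archived recordings often
  carry hours of pre/post-sleep wake and the trimming convention of any
  given study is rarely recoverable.
* All randomness flows through explicit integer seeds; child streams are
  derived with a fixed integer recurrence kept below 2³¹, and seeded
  sections restore the caller's RNG state.

## Problem sizes

The Monte-Carlo checks run on cohorts of 12 subjects (2 per age × sex
cell) with 5 epochs per stage — 300 epochs per cohort, the smallest design
in which every subgroup still holds 10 epochs per stage after balancing,
so the subgroup experiment remains splittable. Effect recovery and null
calibration each use 20 cohort seeds; estimator oracles use 100 random
discrete tables and 30 000-sample Gaussian pairs; the ANOVA type-I rate
uses 1000 null replicates. These sizes are the package's standard
verification conditions and are reproduced end-to-end by
`scripts/acceptance.R`.

## Known limitations

* The histogram MI estimator is biased at epoch length; comparisons are
  valid because N and binning are constant within an analysis, but
  absolute per-epoch MI values should not be compared across different
  `n_bins` or epoch lengths.
* Epoch-level splitting overstates staging accuracy relative to
  subject-level generalization.
* EDF support covers continuous (EDF/EDF+C) files with 16-bit samples —
  deliberately minimal; discontinuous files and non-EEG channels are out
  of scope.
* The group statistics correct for multiplicity within each omnibus
  family only, not across the 6 bands × multiple factors tested; a
  study-wide correction would be stricter.
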