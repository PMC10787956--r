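---
title: "Methods: band-power and entropy screening of REM-sleep EEG for bruxism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: band-power and entropy screening of REM-sleep EEG for bruxism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(remband)
```

## The analysis in one paragraph

Sleep bruxism — involuntary grinding or clenching of the teeth during
sleep — leaves a spectral signature in the sleep EEG: during REM sleep,
bruxism patients show relatively less slow (theta) activity and relatively
more fast (alpha, beta) activity than healthy controls. `remband`
implements a single-channel screening pipeline built on that signature.
Each 30-second REM epoch of one bipolar EEG channel is decomposed into the
four classical bands (δ 1–4, θ 4–8, α 8–13, β 13–30 Hz) with a Daubechies-5
discrete wavelet transform; Welch's method turns each band-limited
reconstruction into absolute and relative band power; together with band
amplitude statistics and sample entropy this yields 28 features per epoch.
Features are screened between groups with rank-sum tests, and epochs are
classified with a CART decision tree ("fine tree" preset) under stratified
five-fold cross-validation, reporting sensitivity, specificity, accuracy
and PPV per channel.

## Epoch extraction

Recordings arrive as EDF files with per-channel sampling rates plus a
hypnogram (`STAGE ONSET DURATION` text annotations). Contiguous REM
annotations are merged into maximal REM intervals, each interval is tiled
with consecutive non-overlapping 30-s windows from its onset, and a
trailing remainder shorter than 30 s is discarded. Tiling never crosses an
annotation boundary, and nothing is resampled or artifact-rejected at this
stage — frequency-selective artifact handling happens implicitly in the
band decomposition, which discards everything below 1 Hz (slow drifts,
ocular artifacts) and above 32 Hz (muscle and line noise).

Epochs from one subject are *not* independent; following common practice
for this design, the screening and classification stages nevertheless
treat pooled epochs as exchangeable. This pseudo-replication caveat is
inherited deliberately and not resolved here; a subject-level
cross-validation switch would be the conservative alternative.

## Wavelet band decomposition

A multilevel DB5 DWT with symmetric boundary extension (depth 8 at 512 Hz,
generally `log2(fs) - 1`) maps the dyadic detail levels onto bands: at
512 Hz, D4 spans 16–32 Hz (β), D5 8–16 Hz (α), D6 4–8 Hz (θ) and D7∪D8
1–4 Hz (δ). The level-8 approximation (< 1 Hz) and D1–D3 (> 32 Hz) are
discarded. Each band is reconstructed by inverting the transform with all
other coefficients zeroed, so the four band signals plus the discarded
residual reproduce the input to numerical precision (verified to a relative
residual below 1e-8).

Two caveats are documented prominently. First, the dyadic α/β edges (8–16,
16–32 Hz) do not coincide with the nominal 8–13 / 13–30 Hz edges. Second,
DB5's subband filters have wide transition bands: probing the analysis
chain with unit-variance single-band noise shows only ~70–80% of a band's
power is attributed back to it, with the remainder scattered mostly into
the adjacent band (`band_leakage_matrix()` measures this 4×4 operator).
Any interpretation of the band features should treat them as "DB5 band"
quantities rather than ideal rectangular-band quantities — exactly as in
the original analysis whose published band tables were produced through
the same operator.

## Band power

Welch's method uses the study configuration: 128-sample periodic Hamming
window, 50% overlap, 256 FFT points, one-sided density scaling, giving 239
segments and a 2-Hz grid on a 30-s epoch at 512 Hz. Segments are *not*
detrended by default: at 512 Hz a segment spans 0.25 s, and removing each
segment's mean would high-pass well into the delta band (on probe epochs it
removed over half of the delta-band power). MATLAB's `pwelch`, the
reference implementation for this configuration, also applies no
detrending; `detrend = "constant"` is available for sensitivity analysis.

Absolute band power (APSD) is the trapezoidal integral of the Welch
density of each *band-reconstructed* signal over its full spectral grid.
Because the reconstruction is already band-limited, its total spectral
power *is* its band power (Parseval); re-integrating over the nominal band
edges instead would discard the spectral spread of the short Welch
segments — a 128-sample window cannot confine 1–4 Hz power to 1–4 Hz — and
systematically bias the slow bands downward. Relative power (RPSD) is each
band's share of the summed four-band power, in percent; it always sums to
100 (± 1e-9) and is invariant under amplitude scaling. `band_apsd()`
remains a general band-range integrator for raw-spectrum work, with
linear interpolation at the band edges so adjacent bands partition the
spectrum without double counting.

## The 28 features

Per epoch and channel, in canonical order: Mean, SD (population), RMS of
each band signal (mV; 12 time-domain features); RPSD per band (%), the
ratios (θ+α)/β, α/δ, α/θ, α/β computed from RPSD (equivalently from APSD —
the common denominator cancels), and APSD per band (12 frequency-domain
features); sample entropy per band (4 nonlinear features). RMS² = SD² +
Mean² holds per band by construction.

Sample entropy uses the standard template-counting definition: with
template length m = 5 and tolerance r = 0.2 × the series' own (population)
SD, SampEn = −ln(A/B) where B counts template pairs of length m within
Chebyshev distance r (self-matches excluded) and A the subset still
matching at length m + 1. The parameterisation "maximum template length 5,
threshold 0.2" is read as evaluating SampEn at m = 5; `all_m = TRUE`
exposes the full profile m = 1…5 for users who prefer the toolkit
convention of reporting every length. Edge conventions (applied identically
by the test oracle): constant series → 0; B = 0 → 0; A = 0 → capped at
ln(B). The counting kernel is C++ (exact integer counts, identical to a
brute-force O(N²) enumeration on every tested series); an epoch costs
roughly a second at 512 Hz.

Degenerate epochs (zero variance, zero band power, a zero ratio
denominator) are excluded with a logged reason rather than emitted as NA
rows, so every epoch ends up in exactly one of the feature table or the
exclusion log.

## Statistical screening

Per channel × feature, group location is compared with the Mann-Whitney
rank-sum test (two-sided, midranks for ties; exact null distribution for
tie-free samples with n ≤ 16, otherwise normal approximation with tie and
continuity corrections). The default policy applies the rank-sum test to
all features, reproducing the reference behaviour where mixed Shapiro-Wilk
outcomes led to non-parametric testing throughout; `policy = "auto"`
instead gates per feature — Welch's t-test when both groups pass
Shapiro-Wilk at α = 0.05, rank-sum otherwise. The Welch (unequal-variance)
variant is the deliberate choice for the parametric branch. Stars mark
p ≤ 0.05 (*) and p ≤ 0.001 (**); no multiple-testing correction is applied,
mirroring per-feature raw p-value reporting.

## Classification

The classifier is CART with the "fine tree" preset: Gini impurity, up to
100 splits, minimum leaf size 1, midpoint thresholds. Growth is greedy
best-first — the frontier node whose best candidate split maximises the
weighted impurity decrease is split next — with deterministic tie-breaking
(lowest feature index, then lowest threshold, then oldest node). Rows with
feature value equal to a threshold route right. Evaluation uses stratified
k-fold cross-validation (k = 5, seeded shuffle, per-fold class counts
within one of proportionality); the confusion matrix is pooled over folds
(micro-averaging) with bruxism as the positive class, and per-fold metrics
are also retained. Pooling was chosen over fold-averaging because it keeps
the four metrics exactly recomputable from one confusion matrix; both views
are available from the fitted object. Cross-validation is at the epoch
level, matching the published epoch counts; epochs of one subject can fall
on both sides of a fold boundary, which inflates estimates relative to a
leave-subject-out design (see the caveat above).

## The synthetic cohort generator

The generator exists so every stage is testable without clinical data. It
emulates the study conditions: two groups of subjects, 30-s REM epochs at
512 Hz, five bipolar channels (F4C4, C4P4, Fp1F3, F3C3, C4A1), REM blocks
interleaved with non-REM filler stages so that epoch extraction faces
distractor annotations, and per-group band-power profiles with lower
relative θ and higher relative α/β in the bruxism group. Per-group default
levels reproduce the published group means (healthy ≈ 65.3/20.6/8.4/5.7%,
bruxism ≈ 65.3/17.5/9.9/7.3% for δ/θ/α/β), with overall amplitude set so
the measured delta-band SD is ≈ 8.3 mV (healthy) and ≈ 7.0 mV (bruxism).

Band components are white Gaussian noise band-limited by exact zero-phase
Fourier masking at the nominal band edges. A Butterworth band-pass was
considered and rejected: in transfer-function form the 1–4 Hz band at
512 Hz is numerically unstable in double precision, and even the stable
bands leak well over 10% of their power outside the nominal range, while
the Fourier mask is exact by construction (≥ 99% in-band at high spectral
resolution). Optional contaminants — a 0.3 Hz drift sinusoid and a 45 Hz
sinusoid — exercise the decomposition's sub-1-Hz and >32 Hz rejection.

Because the published group profiles are themselves *measurements through
the DB5 + Welch chain*, profiles constructed with `calibrate = TRUE` (the
default for `default_group_profiles()`) pre-multiply component powers by
the inverse of the measured leakage matrix, so that what the pipeline
measures on the synthetic cohort reproduces the requested values (to
within ~0.7 percentage points at 100 epochs/group) rather than the
pre-leakage values. Uncalibrated profiles (`calibrate = FALSE`) make the
generated signal's true band content match the targets instead; both are
legitimate, they answer different questions.

What the generator does *not* emulate: sleep-EEG morphology (spindles,
K-complexes), 1/f spectral slopes within bands, inter-subject variability
(all subjects of a group share one profile), annotation errors, or
imbalanced epoch counts (equal counts per subject by default — imbalance is
a configuration option, not a default, since no imbalance handling is part
of the modelled analysis). Passing tests on synthetic cohorts therefore
demonstrate that the pipeline measures what the generator encodes — band
structure, group contrasts, separability — not that real recordings would
yield any particular accuracy.

## Numerical choices and degenerate inputs

* DWT boundary handling is symmetric extension (periodisation would
  wrap 30-s epochs onto themselves); reconstruction lengths are tracked
  per level so odd lengths invert exactly.
* Band-edge bins: `band_apsd()` interpolates the density at the band
  edges, so [8,13] and [13,30] partition the spectrum exactly.
* Sampling rates must be powers of two ≥ 64 Hz for the dyadic band map;
  anything else raises an unsupported-rate error rather than silently
  remapping.
* EDF quantisation range is ±8× the largest component amplitude per
  channel, keeping quantisation error below 0.1% of signal SD; EDF headers
  carry a fixed timestamp so identically-specified cohorts are
  byte-identical on disk.
* Population SD is used throughout the feature stage (immaterial at
  N = 15,360, documented for exactness of the RMS identity).
* Tests are sized to run on one CPU in minutes: oracle sweeps use series
  up to length 500 and datasets up to 8 rows, the recovery experiment uses
  100 epochs per group on one channel, and the null-cohort checks use 8-s
  epochs at 128 Hz.

## Known limitations

Single-channel analysis inherits every caveat of the source design: two
patients versus four controls, epoch-level pooling and CV, raw p-values
over 28 correlated features, and band quantities filtered through DB5's
leaky subbands. The package reproduces the analysis faithfully and
documents these limits; it does not attempt to fix them.
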