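---
title: "Automated EEG artifact removal: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated EEG artifact removal: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

eegclean implements a fully automated preprocessing chain for continuous
multichannel EEG with high artifact load — the situation typical of
developmental and clinical recordings, where long clean stretches do not
exist, eye channels are unavailable, and manual review does not scale.
This vignette is the package's own account of the methods: the model each
stage assumes, the tunable parameters and why their defaults are what they
are, the numerical choices that required a decision, and what the bundled
synthetic data can and cannot tell you about behaviour on real EEG.

## The processing chain

Every file passes through the same fixed stage order:

1. zero-phase **high-pass filtering** at 1 Hz (a 1–249 Hz band-pass for
   files sampled at 500 Hz or above),
2. **channel-subset selection** against the ICA sample budget,
3. **line-noise removal** by multitaper sinusoid regression,
4. two-pass joint-probability **bad-channel detection**,
5. **wavelet-enhanced ICA** (W-ICA): every independent component is
   wavelet-thresholded and the surviving large-amplitude content is
   subtracted as artifact,
6. a second ICA with **six-feature automated component rejection** at
   artifact probability 0.5,
7. optional **segmentation** with either segment rejection or per-segment
   channel repair,
8. spherical-spline **interpolation** of the bad channels, and
9. **re-referencing** (average, or a user channel set).

One row of data-quality metrics per file is appended to the processing
report; all probability metrics describe the components kept at stage 6,
before any segment-level processing.

## Filtering

Filters are Hamming windowed-sinc FIR designs with a transition band of
about 1 Hz at the 1 Hz edge. The low-pass prototype is normalized to unit
DC gain and the high-pass obtained by spectral inversion, so the high-pass
has *exactly* zero DC gain and half-amplitude response at 1 Hz. Because the
impulse response is symmetric, a single pass with exact group-delay
compensation is zero-phase; the signal is extended by reflection so the
compensation never runs off the data. A 1 Hz high-pass is assumed
throughout: both the line-noise F-test and ICA behave best on drift-free
input, and the bad-channel power statistic starts its band at 1 Hz.

## Line-noise removal

Notch filtering removes genuine EEG together with the line; the package
instead fits a deterministic sinusoid per sliding window (4 s windows, 1 s
step) with multitaper regression. Slepian tapers with time-bandwidth
NW = 4 (seven tapers, 2 Hz taper bandwidth over the 4 s window) yield the
Thomson F-statistic at each frequency of a 0.05 Hz grid within ±2 Hz of
the configured target (60 Hz default; 50 Hz, or a harmonic list, via
`line_noise_config()`).

Two numerical choices matter here:

* **Consensus frequency.** The scan runs per window, but the subtracted
  sinusoid uses one frequency per channel — the median of the
  per-window scan winners that reached significance (p < 0.01, F(2, 2K−2)).
  Per-window frequencies would differ by one or two grid steps between
  windows, and a 0.05 Hz error integrates to a large phase ramp over a 4 s
  window; the residual sidebands would stay well above the noise floor.
  With the consensus frequency, amplitude and phase are re-estimated per
  window and subtraction reaches the local noise floor.
* **Overlap smoothing.** Window contributions are blended with sigmoidal
  weights of steepness tau = 100 over the 3 s overlap — effectively a hard
  hand-over at the overlap midpoint. The first and last windows keep full
  weight at their outer edges, where no neighbouring window exists;
  without this the first and last ~1.5 s of a file would never be cleaned.

Windows in which the regression coefficient never reaches significance
contribute nothing, so line-free signal passes through bit-identically.

## Bad-channel detection

Each channel is summarized by its mean log10 Welch power over 1–125 Hz
(2 s Hamming segments, 50% overlap; the band is clipped to Nyquist − 1 for
low sampling rates, and all-zero channels are floored rather than mapped
to −Inf). A channel is rejected when its *normed joint probability* is an
outlier: the package estimates the empirical density of the per-channel
summaries with a leave-one-out Gaussian kernel (robust `nrd0` bandwidth),
takes the signed-log-compressed negative log density as the improbability
score, and flags a channel when **both** the score's z and the raw value's
z exceed 3. The conjunction anchors the "3 standard deviations from the
mean" rule on the value scale while the density term keeps flags specific
to genuinely isolated values: leave-one-out stops an extreme outlier from
hiding under its own kernel, the robust bandwidth stops it from widening
everyone's kernels, and the log compression stops two simultaneous
outliers from diluting each other's z-scores. The evaluation runs twice —
the second time on the survivors — because a grossly bad channel inflates
the first pass's spread and can mask a moderately bad one. With fewer than
8 channels a plain z-score on the values is used (with a warning).

Flagged channels are excluded from every later stage and reconstructed by
spherical-spline interpolation at stage 8, so the delivered channel set is
always complete; their identities are listed in the report.

## The ICA engine

Both decompositions use natural-gradient extended Infomax on centered,
PCA-sphered data: learning rate 0.00065/log(K), block size
ceil(min(5·log(N), 0.3·N)), annealing ×0.98 whenever the gradient
direction turns by more than 60°, stop at a squared weight change below
1e-7 or 512 passes. Kurtosis signs (supergaussian vs subgaussian
nonlinearity per component) are re-estimated every block from 6000
subsampled points with momentum 0.5 and bias 0.02, which is what lets the
same algorithm isolate both spiky artifacts and any residual line noise.
Rank-deficient input is reduced to its effective rank (relative eigenvalue
tolerance 1e-7) with a warning. The weight updates run in compiled code
with an internal xorshift RNG, so a decomposition is bit-reproducible from
its seed on a given platform; the seed is a mandatory argument, is stored
in the result, and is written into the post-ICA intermediate file, because
different seeds legitimately give different component orderings and the
analysis record must say which one was used.

## W-ICA

All components from the first decomposition are transformed with a
stationary (undecimated) Coiflet order-5 wavelet, implemented as the
à trous scheme by FFT circular convolution after symmetric padding to a
multiple of 2^L. The depth is L = round(log2(fs/16)), which places the
deepest detail band's lower edge near 8 Hz (L = 4 at 250 Hz, 5 at 500 Hz)
and the finest band up to Nyquist, i.e. the detail bands span roughly
8–125 Hz at 250 Hz. "Order 5" was chosen over "depth 5" for the wavelet's
ambiguous "level 5" label because the depth is rate-dependent in this
design; both are exposed as arguments.

One global threshold per file is computed from the finest-level detail
coefficients of *all* components pooled:
T = (median|D|/0.6745)·sqrt(2·ln N), the universal threshold with a
robust noise-scale estimate. Every band is then soft-thresholded —
including the approximation band. The content that survives thresholding
is reconstructed as the artifact stream, remixed to channel space and
subtracted; no component is removed outright, and by linearity
cleaned + artifact equals the input sample-exactly. Thresholding the
approximation band is deliberate: blinks and discontinuities carry most of
their energy below 8 Hz, and the two limit cases then hold exactly
(T = ∞ leaves the input untouched; T = 0 takes the entire centered signal
as artifact). The cost is that any sub-8 Hz excursion beyond ±T is shaved
into the artifact stream; the white sensor-noise floor of real EEG keeps T
well above genuine low-frequency EEG amplitudes in practice, and the
signal-preservation tests quantify the effect.

## Component rejection

Components of the second decomposition are scored on six features: mean
absolute local skewness over 15 s windows (trailing windows of at least
5 s included); mean log10 alpha-band (8–13 Hz) power; the slope λ of a
least-squares fit of log10 P against −log10 f sampled at 2, 5, 8, 13, 30
and 75 Hz (75 clipped to Nyquist − 5 below 160 Hz); the mean squared
residual of that fit against the observed log-spectrum in 8–15 Hz; the log
range of the unit-norm scalp map; and the log norm of the minimum-norm
current density ĵ = Lᵀ(LLᵀ + αI)⁻¹v explaining the map. Scalp maps are
read from the mixing-matrix rows of the 19 mapped 10–20 anchor channels
(at most 4 may be missing after bad-channel removal). The head model
behind the last feature is deliberately minimal: 200 grid dipoles with
three orientations on a 0.8-radius shell of a unit homogeneous sphere,
the analytic Legendre-series leadfield, average-referenced, with
α = 1e-4·trace(LLᵀ)/19 — the smallest model that makes dipolar maps cheap
and scrambled maps expensive to explain.

The features feed a standardized logistic head; a component is rejected
when its artifact probability strictly exceeds 0.5. Published trained
weights for this feature set do not exist in usable form, so the package
ships weights calibrated on its own labeled synthetic corpus
(`generate_labeled_components()`: neural alpha, neural broadband, blink,
EMG, line, discontinuity) via `calibrate_classifier()` — a scripted,
seeded, ridge-regularized logistic fit (glmnet, α = 0, λ = 0.02; the
classes are separable and an unpenalized fit would diverge). The
calibration is reproducible from its seeds and externally trained weights
can be supplied as a JSON file with the same structure. Probabilities from
these weights are meaningful for ranking and thresholding synthetic-like
components; they are not estimates of human-labeller agreement on real
EEG.

## Segmentation

Resting data is cut into consecutive fixed-length windows from sample 0
(trailing partial window dropped); event data into per-event windows,
which may overlap. Sample indices are 0-based and intervals half-open.
Two mutually exclusive artifact options follow. **Segment rejection**
flags a segment when any evaluated sample crosses ±40 µV (the default
reflects the smaller amplitudes left after W-ICA and component rejection),
or when a channel's segment RMS is a joint-probability outlier either
against that channel across segments or against the other channels within
the segment (same estimator and z > 3 rule as bad-channel detection;
needs at least 8 segments); all marked segments are rejected in one step,
and an ROI channel list restricts evaluation. **Per-segment repair**
scores four per-channel criteria within each segment — variance, median
absolute first difference, amplitude range, and |segment mean − channel
grand mean| — with the same robust joint-probability z as the other
detectors (plain z-scores over ~19 channels, multiplied across four
criteria and every segment, flag clean tail channels far too often), and
spherical-spline-interpolates channels with any |z| > 3 inside that
segment only, preserving the segment count for short files. This step is
deliberately liberal: with four correlated criteria tested across ~19
channels in every segment, even ideal clean segments are repaired at a
rate of several percent — an acceptable cost, since interpolating one
channel in one segment discards far less information than rejecting the
segment.

## Spherical-spline interpolation

The scalp field is modelled as a constant plus a spline on the sphere with
stiffness m = 4 and Legendre series truncated at order 7. Numerically the
fit is solved in the factored (Mercer) form — real spherical harmonics up
to degree 7, each degree scaled by (n(n+1))^(−m/2), with a minimum-norm
SVD solve (relative tolerance 1e-12) — rather than through the classic
kernel Gram matrix. The two are identical in exact arithmetic, but the
Gram matrix squares the condition number: with electrodes on a hemisphere
its singular values fall to ~1e-11 of the largest, and reconstruction
error plateaus near 1e-3. In factored form any field in the span of the
truncated kernel — in particular any spherical-harmonic field of degree
≤ 7 — is reproduced at held-out electrodes to solver precision. The
default is unregularized (`lambda = 0`), preserving that exactness; a
small ridge (~1e-6) trades it for robustness to very shallow sources and
is exposed as an argument.

## The synthetic generator

`generate_recording()` emits data as an exact sum of a clean signal and
labeled artifacts, with sample-aligned masks, channel footprints and
planted bad-channel identities, all driven by one seed. The clean signal
is per-channel 1/f noise (default 10 µV RMS, exponent 1) with ±10%
per-channel gain jitter, a 4 µV white sensor-noise floor, and dipolar
narrowband sources projected through the same sphere head model used by
the classifier. The two realism terms are load-bearing, not cosmetic: the
sensor-noise floor sets the scale of the wavelet threshold (without a
high-frequency floor T collapses and W-ICA soft-clips genuine
low-frequency EEG), and the gain jitter gives clean channels a realistic
power spread (with bit-identical channel powers, bad-channel z-scores
amplify numerical residue). Artifacts: frontal-weighted biphasic blinks of
0.3–1 s at 100–200 µV, Hanning-windowed 20–100 Hz EMG bursts on temporal
channels, a common line sinusoid with per-channel gain, sub-0.5 Hz drift,
and dead (exactly zero) or broadband-noisy channels. Default amplitudes
breach the ±40 µV segment threshold the way heavily contaminated
recordings do.

What the generator does *not* emulate: volume-conducted correlated
background (channels share only the dipolar sources), non-stationary
artifact morphology, electrode drift-and-recover episodes, pediatric
spectral peaks outside alpha, or any specific real dataset. Passing tests
therefore demonstrate that each stage does what its model claims under
controlled conditions — recovery of planted structure, exact invariants,
calibrated error rates — not that quality metrics on a particular clinical
cohort will match any published distribution.

## Problem sizes and determinism

The test-suite and acceptance problem sizes are chosen as the smallest
that exercise each claim meaningfully: ICA recovery uses 10 sources mixed
into 19 channels at 250 Hz for 60 s (the sample budget for 19 channels,
30·19² = 10,830 samples, is comfortably met), detection studies use
39-channel 60 s fixtures over 10–20 seeds, classifier validation uses 50
held-out corpus seeds, and end-to-end pipeline checks use a 19-channel
50 s file. Every stochastic step — generator draws, decomposition
shuffles, calibration corpora — flows from explicit seeds, and identical
configuration reproduces the processing report bit-for-bit.

## Known limitations

* ICA decompositions differ across seeds; only the per-seed result is
  reproducible. The report's component metrics inherit this.
* The shipped classifier weights are a synthetic-corpus calibration, not a
  reimplementation of any published classifier's training; transfer to
  real EEG is unvalidated.
* EDF export quantizes to 16 bits over ±3276.7 µV (0.1 µV steps) and
  stores events only in the native sidecar format.
* The line-noise stage assumes the line frequency is stable within a file;
  a drifting line would be attenuated but not removed to the floor.
* Spherical-spline repair degrades toward the montage boundary, where
  interpolation becomes extrapolation; leave-one-out error figures in the
  tests quantify the interior case.
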