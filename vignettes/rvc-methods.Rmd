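---
title: "Response variance curves for prefrontal ERP variability: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Response variance curves for prefrontal ERP variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvcerp)
```

## The model

An auditory oddball session yields, per subject, epoched two-channel
(Fp1/Fp2) EEG: 64 rare target tones and 256 frequent standard tones,
sampled at 250 Hz over [−200, 800) ms around each stimulus onset. After
preprocessing, the response variance curve (RVC) at each post-stimulus time
point is the unbiased across-trial sample variance of the single-trial
amplitudes — the pointwise spread of individual trials around the average
ERP. Stable responders have low, flat RVCs; unstable attention or degraded
neural timing inflates the curve, particularly under the P2 (sensory
attention, 150–300 ms) and P3 (attention allocation / memory updating,
300–600 ms) windows.

From each window × condition × channel curve we extract AMPV (peak
variance, µV²), LATV (peak latency, ms), FALV (50% fractional-area latency,
ms) and AUCV (trapezoidal area, µV²·ms). Channel-averaged values feed the
group statistics; per-channel values feed the normalized asymmetry index
(Fp2 − Fp1)/(Fp2 + Fp1), which is bounded in [−1, 1], antisymmetric under
channel swap, and positive when the right prefrontal site is the more
variable one.

## Preprocessing chain and its parameters

The stage order is fixed: segmentation → baseline correction (subtract the
per-trial mean over [−200, 0) ms) → behavioral-correctness selection
(targets identified; standards with no response) → artifact rejection →
smoothing.

* **Artifact threshold, 100 µV.** A trial is clean iff every sample on
  every channel satisfies |x| ≤ 100 µV. The joint (both-channel) rule
  defines the retained trial set so the channels stay paired; per-channel
  masks are also reported and drive the clean-trial counts, since the
  subject-level exclusion wording ("no clean trials in any of the two
  channels") is inherently per-channel.
* **Smoothing, 9-point centered moving average** (36 ms at 250 Hz), applied
  to single trials before the variance is computed — variance of smoothed
  trials is well-defined, whereas smoothing an already-computed variance
  curve is a different (exposed but non-default) quantity. Edges shrink the
  window to the available samples rather than padding or reflecting, so no
  data is invented and constant signals are exactly preserved.
* **Epoch grid.** Half-open [−200, 800) ms, 250 samples, 0 ms on-grid. The
  window boundary at 300 ms belongs to both the P2 and P3 windows
  (inclusive membership); the two windows are analyzed independently and
  the shared sample changes AUCV by at most one trapezoid.

## Inclusion screens

Subjects are excluded with exactly one primary reason, in order of
precedence: `no_clean_trials` (some condition × channel has zero clean
trials), `below_half_clean` (< 50% clean trials in some cell; exactly 50%
is included), `no_discernible_peak` (some analyzed per-channel RVC has no
strict interior maximum in its window), `extreme_variability` (some
channel-averaged measure falls outside the Tukey fences Q1 − 3·IQR,
Q3 + 3·IQR computed across the cohort). The peak and fence rules default to
"any analyzed curve/measure" because the source methodology does not state
a subset; both are configurable.

## Numerical choices

* Unbiased (n − 1) variance; with ≥ 160 clean trials the denominator choice
  is numerically minor but it must be fixed for exact oracle tests.
* Peak ties resolved to the earliest time (determinism).
* FALV interpolates linearly on the cumulative trapezoid; when the window
  area is zero, FALV is undefined and reported missing.
* Welch–Satterthwaite degrees of freedom for Welch's t; the `auto` variant
  selects Welch when a two-sided F-test of variance equality rejects at
  0.05 (the source reports both test types per row without stating its
  selection rule).
* Logistic odds ratios default to z-scored predictors (per-SD OR), because
  published ORs of nearly identical magnitude (~1.15–1.22) across measures
  whose physical units differ by orders of magnitude (µV² vs µV²·ms vs ms)
  are only coherent for standardized predictors; per-raw-unit fits remain
  available via `scaling = "raw"`. Sex is coded male = 1. Intervals are
  95% Wald (deterministic, standard reporting default).

## The synthetic-data generator

The generator emulates the oddball cohort structure: per group (CN /
MCI-like), demographics are drawn from published group marginals (age
72.06 ± 6.36 vs 73.82 ± 6.54 y; MMSE 27.68 ± 1.90 vs 26.31 ± 2.68; five
cognitive-domain scores, sex proportions, education), independently per
field since only marginals are published.

Each trial is a sum of two Gaussian bumps plus noise:

* P2: 5 µV at 200 ms (SD 25 ms), target gain 1.2;
* P3: 8 µV at 450 ms (SD 50 ms), target gain 1.5 — an elderly prefrontal
  P300 sits late (400–500 ms) and this separation keeps its variance
  shoulder out of the P2 window for typical subjects;
* trial-level jitter: amplitude SD 1.0 (CN) / 1.5 (MCI) µV, latency SD
  20 / 30 ms — the inflated-variability group effect; no effect size in
  physical units is published, so these are chosen for clear testability;
* subject-level heterogeneity: component means vary across subjects
  (amplitude SD 1.5 µV, latency SD 15 ms) and each subject's jitter SDs
  carry a mean-preserving lognormal multiplier (CV 0.3). Without this the
  within-group measure distributions are nearly degenerate and logistic
  models separate completely — real cohorts are heterogeneous;
* right-channel imbalance: trial deviations on Fp2 are scaled by 1.1 (CN) /
  1.3 (MCI), plus a subject-level SD of 0.15, giving positive asymmetry
  indices in both groups and larger ones in the MCI-like group, with a
  known sign for tests;
* white Gaussian noise, SD 3 µV (a 1/f option exists; no noise spectrum is
  published); artifact trials (rate 0.02) get one sample forced to ±150 µV
  so they always trip the ±100 µV screen; behavioral errors (rate 0.05)
  flag trials incorrect.

Determinism: one master seed drives the demographic draws and one derived
sub-seed per subject, so cohorts are bit-identical across runs and
insensitive to subject order.

**What a green test does not establish.** The generator reproduces the
*statistical skeleton* of the task (trial counts, jitter, artifacts, group
contrasts), not real EEG: no oscillatory background with realistic spectra,
no ocular/muscle artifacts with physiological morphology, no habituation or
fatigue drifts, no covariance between demographics and neural parameters
(age does not modulate jitter), and component shapes are exactly Gaussian.
Its discernible-peak exclusion rate (~20% of subjects at defaults) is also
higher than the ~6.5% reported for the real cohort — weak-component
subjects in the simulation fail the strict interior-maximum rule more
often. Green acceptance tests therefore establish correctness of the
pipeline's arithmetic and its directional sensitivity to planted effects,
not clinical validity.

## Degenerate inputs and edge behavior

Zero jitter and noise give identical trials and an identically zero RVC
(FALV missing); fewer than two clean trials in any analyzed cell raises a
typed insufficient-data condition that maps onto the subject-exclusion
path; a degenerate cohort distribution (IQR = 0) disables the fence screen
with a warning instead of flagging everyone; events too close to a
recording edge are skipped with a warning during segmentation; EDF signals
are quantized to 16 bits over ±1000 µV (~0.03 µV resolution), which is far
below the noise floor of any realistic recording.

## Known limitations

Single-trial latency estimation (e.g. Woody filtering) is deliberately out
of scope — variability is defined through the RVC only. The EDF layer
supports uniform-rate two-channel recordings with annotation events, not
the full zoo of EDF variants. The published cohort-level effect sizes
(t-statistics of −2.3 to −3.1 on variability measures, ORs of 1.15–1.23)
are not reproducible without the undeposited raw EEG; the package instead
anchors correctness on the recomputable summary-statistic examples and on
parameter recovery in its own stated synthetic world.
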