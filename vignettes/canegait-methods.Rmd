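---
title: "Cane-mounted IMU gait analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cane-mounted IMU gait analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canegait)
```

`canegait` analyses walking trials recorded by an IMU built into a cane:
it detects cane ground contacts, extracts ten per-trial features, compares
them between frail and robust older adults, and benchmarks five
classifier families for frailty screening. This vignette explains the
models and the choices behind every tunable number; it states no
empirical result beyond what the package's tests and acceptance script
compute themselves.

## Signal model and preprocessing

Input trials are 6-channel time series — tri-axial acceleration (m/s²)
and angular velocity (deg/s) along the vertical (VT), anteroposterior
(AP) and mediolateral (ML) axes — sampled at 120 Hz. The reader treats
channels as already expressed in the anatomical frame and performs no
unit conversion or orientation correction: sensor-to-anatomical alignment
is declared solved upstream, because inventing a sensor-fusion stage here
would add un-testable science.

**Filtering.** A fourth-order Butterworth low-pass at 10 Hz, applied
forward and backward (zero phase), keeps detected event times aligned
with the raw signal. `signal::filtfilt` applies no edge handling, so a
constant channel would acquire O(1) edge transients; `lowpass_filter()`
therefore implements the conventional zero-phase scheme itself on top of
`signal::butter`: odd-reflection padding of length 3·order with
steady-state initial conditions. A constant input passes with unit gain
to machine precision, and the double pass attenuates by the squared
single-pass magnitude, 1/(1 + (f/f_c)^8) at the defaults — about 1.5e-4
in amplitude for a 30 Hz tone. Strongly attenuated tones still leak near
the first/last ~0.5 s because reflection padding cannot represent them;
trials carry lead-in and tail margins, so no contact lands there.

**Contact detection.** The jerk norm ‖(a[n] − a[n−1])·fs‖₂ of the
filtered acceleration spikes at every cane impact. A first (not centred)
difference keeps those spikes sharp. Peaks above mean + k·sd (default
k = 3) are accepted greedily in descending height with a minimum
separation of 0.5 s — a safe refractory period when stride times are
near one second — then sorted. A trial with no accepted peak raises a
typed "no contact" condition and is excluded, mirroring the exclusion of
unmeasurable recordings in the underlying study design.

**Windowing and cycles.** 512 samples (~4.27 s) are taken from the first
detected contact; trials too short for a full window are excluded and
counted. The stride (gait cycle) is the half-open interval between
successive contacts; only complete cycles inside the window enter the
per-cycle features. The alternative — using the partial trailing cycle —
was rejected because a truncated cycle biases RMS toward whichever gait
phase it happens to contain.

## Features

Per axis: RMS of the acceleration and the peak unsigned angular velocity
are computed per cycle and averaged over cycles; the mean power frequency
(MPF) is computed once per axis on the full 512-sample window; stride
time is the mean cycle duration.

Two decisions deserve note:

* **Mean removal.** The per-axis window mean is subtracted before both
  RMS and FFT (`demean_window = TRUE`). Without it the VT channel's
  ~9.8 m/s² gravity offset dominates the RMS and leaks into the low
  bins of the spectrum. The flag is exposed for sensitivity analyses.
* **MPF definition.** The band 0.5–10 Hz is fixed; the estimator is the
  standard power-weighted mean (spectral centroid) over bins whose
  centres lie inside the band, endpoints inclusive. At 512 samples and
  120 Hz the bin spacing is 0.234375 Hz, so bins 0–2 (≤ 0.47 Hz) are
  excluded and bin 42 (9.84 Hz) is the last included. The window is the
  periodic Hamming form w[n] = 0.54 − 0.46·cos(2πn/L), whose leakage is
  symmetric for on-bin tones — hence an on-bin tone's centroid equals its
  frequency and two equal tones average to their midpoint, the identities
  the test suite asserts.

Peak angular velocity is max |ω|; no sign convention is imposed on the
swing direction.

## Group statistics

Each feature is compared across groups with the Mann–Whitney U test:
midranks for ties, U reported as min(U₁, U₂), and the tie-corrected
normal approximation for Z. The effect size is r = |Z|/√N with the
conventional banding negligible/small/moderate/large at 0.1/0.3/0.5
(left-closed intervals, so r = 0.3 is moderate). The Shapiro–Wilk test
(delegated to `stats::shapiro.test`) is reported as a screen only — the
comparison proceeds nonparametrically regardless — and no multiple-testing
correction is applied across the ten features, matching the original
protocol; the report should be read with that caveat.

One numerical choice departs from the "no continuity correction"
convention some statistical packages use for the *p*-value. The package
always computes **Z uncorrected** (so r matches the conventional
definition), but the default p-value applies the 0.5 continuity
correction, as `stats::wilcox.test` does. The reason is measurable: over
every achievable statistic at group sizes 5–9 (total ≤ 14), the
continuity-corrected p stays within 0.017 of the exact enumeration
p-value (two-sided tail including the observed value), whereas the
uncorrected p deviates from *any* standard exact convention by up to
0.07–0.20 at those sizes. `continuity = FALSE` restores the uncorrected
p for compatibility, and `exact = TRUE` computes the full-enumeration
p-value whenever C(N, n₁) is feasible.

## Classification

The five families and their fixed hyperparameters follow the study
design: decision tree capped at 5 splits (grown with `rpart` at cp = 0,
then pruned back to the largest subtree with ≤ 5 splits); LDA
(`MASS::lda`); k-NN on z-scored features (`class::knn`, k searchable
over 1–25); Gaussian-kernel SVM on z-scored features (`e1071::svm`,
cost and kernel width searchable on log₂ scales); and logistic-loss
boosting of depth-1 trees with 243 cycles at learning rate 0.59256
(`xgboost` with `binary:logistic`). The last model is often labelled a
"random forest" in clinical ML reports even when the described procedure
is LogitBoost; the package implements the described procedure.

Cross-validation uses ten folds whose sizes differ by at most one.
`mode = "trial"` reproduces the leakage-prone protocol in which trials
of one subject may appear on both sides of a split; `mode = "subject"`
keeps each subject's trials together (greedy balancing by trial count)
and is the methodologically sound alternative. On cohorts with
within-subject correlation the subject-grouped accuracy is systematically
no higher than the trial-random accuracy — the acceptance suite
quantifies exactly this leakage.

Normalization is fitted on each training split only, with the sample
(n−1) standard deviation; constant features map to zero with a warning.
This deliberately departs from whole-dataset normalization (itself a mild
leak); fitting per split is the defensible default for a reusable tool.

Metrics: accuracy = 1 − misclassification rate; precision, recall and F1
from the confusion matrix at a 0.5 score threshold, with zero-denominator
ratios reported as absent (`NA`) rather than zero; AUC by the rank
(tie-½) form, equal to the probability that a random positive outscores a
random negative and invariant under monotone score transforms. Because
fold-averaged metrics and aggregated-matrix metrics answer different
questions (and published tables sometimes mix them), both are reported.
The randomized hyperparameter search (default budget 30, seeded) always
includes the default configuration, minimizes the mean fold
misclassification rate, and is non-nested — tuned and reported on the
same folds — matching the original protocol; nested evaluation can be
obtained by wrapping `run_classification` in an outer split.

## The synthetic cohort generator

No public recordings exist for this instrument, so `simulate_trial()`
generates the signal class the pipeline assumes:

* stride periods i.i.d. normal (mean 1.10 s, sd 0.05 s) truncated at
  ±3 sd, with a stride-phase function advancing 2π per stride;
* per axis, a four-harmonic oscillation of the stride frequency with
  amplitudes a_vt = 2.0, a_ap = 1.5, a_ml = 0.8 m/s² (robust preset) and
  weights summing to one — values typical of cane-shaft accelerations at
  comfortable walking speed;
* harmonic phases fixed as gait-pattern constants with a small per-trial
  jitter (sd 0.2 rad). Phase-locking to the contact is deliberate: with
  phases drawn freshly per trial, the overlap between impact and
  oscillation fluctuates so much that trial-level RMS varies by ~15%
  even at fixed parameters, which no fixed-gait-pattern interpretation
  supports;
* an exponential impact transient on the acceleration channels at every
  contact (amplitude 8 m/s² on VT, scaled 0.4/0.25 on AP/ML, decay
  τ = 50 ms). A 50 ms ring-down matches impact transients reported for
  walking aids; it also keeps the filtered pulse asymmetric enough that
  the jerk peak falls consistently on its rising edge (one sample before
  the onset), rather than alternating between edges as a very short
  pulse does after 10 Hz filtering;
* a raised-cosine angular-velocity swing per stride scaled to
  g_vt/g_ap/g_ml = 30/60/25 deg/s — the cane swings mainly in the
  sagittal plane, so AP dominates;
* gravity (9.80665 m/s²) on VT, white noise (0.05 m/s², 0.5 deg/s).

**Group presets.** The frail preset multiplies robust amplitudes by
calibrated ratios (a_vt and impact ×0.9546, a_ap ×0.9015, g_ap ×0.9233,
g_vt ×0.9697) and shifts the VT harmonic weights toward higher harmonics
(0.45/0.28/0.17/0.10 vs 0.55/0.25/0.12/0.08), raising the VT MPF. The
ratios are derived, not fitted: writing the trial-level log-feature
standard deviation as the combination of subject-level (0.10) and
trial-level (0.05) log-normal variability plus the measured extraction
noise, the target rank-biserial separation for an effect of size r at
the 37/94 composition gives a required log-difference
Δ = √2·σ·Φ⁻¹(AUC_target); the amplitude ratios are exp(−Δ) after
accounting for the share of signal power each parameter controls
(impacts scale with a_vt so the VT contrast is not diluted by
group-invariant impact power). Targets were the published effect sizes
r = 0.36 (RMS-VT), 0.29 (RMS-AP), 0.30 (PAV-AP). The resulting VT-MPF
contrast is stronger than its published counterpart (r ≈ 0.18); it was
left so deliberately, because the direction pattern — not the MPF effect
size — is the validated property, and weakening it would make the
direction test fragile.

**Cohort structure.** Defaults are 14 frail and 31 robust subjects with
37 and 94 trials allocated as evenly as possible. Each subject draws an
amplitude multiplier (log-normal, sd 0.10) applied to all amplitudes and
a stride-time multiplier (sd 0.06); each trial draws a further amplitude
multiplier (sd 0.05). Questionnaire answers are Bernoulli with
negative-answer probability 0.85 (frail) / 0.15 (robust) per item, which
makes the ≥3-negative rule agree with the generating group for ~97% of
subjects. The manifest carries the generating group as the label by
default so the cohort composition is exact; `label_source = "kcl"`
switches to questionnaire-derived labels.

**What the generator does not emulate.** Turning segments, terrain,
cane–body coupled dynamics, non-stationary fatigue drift, and realistic
cross-axis coupling. One consequence is visible in the worked example:
because a single subject-level factor scales all amplitudes, ratios of
features are nearly noise-free, and a linear classifier can reach
accuracies no real cohort would support. Passing classification tests
therefore validates the *machinery* (folding, normalization, scoring,
aggregation), not clinical attainability of any accuracy level.

## Problem sizes and determinism

Every stochastic routine takes an explicit seed; cohorts, trials, fold
assignments and searches are pure functions of it (`derive_seed` expands
one top-level seed into named per-stage substreams). The validation
suites use 50 trials for contact recovery, 100 cohorts (tests) or 50
cohorts (acceptance script) for effect-size recovery, 100 enumerated
fixtures for the p-value comparison, and 20 seeds for the null-AUC and
leakage properties — sizes chosen so the whole suite completes in a few
minutes on one core while keeping Monte-Carlo error well inside the
asserted margins.

## Known limitations

* The anatomical-frame assumption shifts orientation errors upstream;
  real deployments need a calibration step the package does not provide.
* The generator's independence and symmetry assumptions make the
  classification task easier than clinical data; see above.
* MPF is computed on one 512-sample window per trial; trials longer than
  ~5 s contribute no further spectral information.
* The exact Mann–Whitney enumeration is limited to C(N, n₁) ≤ 2·10⁵;
  beyond that only the asymptotic p is available.
* No multiple-testing correction across features, by protocol fidelity.
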