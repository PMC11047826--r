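---
title: "Methods: from raw inertial signals to a neuropathy screening call"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw inertial signals to a neuropathy screening call}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnscreen)
```

## Overview

`dnscreen` estimates the probability that a subject has diabetic
peripheral neuropathy from six-axis inertial recordings (tri-axial
acceleration in g, tri-axial angular velocity in deg/s; sensors on the
backs of both hands and both feet) of six standardized neurological
movement exercises. The pipeline is: orientation-invariant norm →
gap interpolation → gravity removal → Welch spectral band features →
(optionally) KDE-based cohort augmentation → one classifier per exercise
→ probability averaging. This vignette documents the model, its
assumptions, the tunable parameters, the synthetic-data generator, and
the numerical choices made where the design was genuinely open.

## Signal processing

**Norm.** Most features derive from the per-sample Euclidean magnitude
of the acceleration triplet, `sqrt(ax^2 + ay^2 + az^2)`. The norm is
invariant under any fixed rotation of the sensor frame, which removes
the dependence on exactly how the wearable sits on the limb — the main
nuisance factor in home use. The gyroscope norm is provided for
symmetry, but the standard chain uses the accelerometer.

**Gap filling.** Streaming losses leave runs of missing samples. Each
interior run of at most `max_gap_samples` (default 25 samples, i.e.
0.25 s at the default 100 Hz) is replaced by a degree-2 polynomial
fitted by least squares to the three nearest valid samples on each side
(six support points). A quadratic reproduces smooth movement locally and
is exact on quadratic trajectories; on a 2 Hz sine sampled at 100 Hz a
4-sample gap is recovered to within 0.02 of the generating function.
Leading and trailing gaps have support on one side only; extrapolation
there is ill-posed, so they are trimmed instead. Longer gaps are an
error naming the gap span — the recording should be repeated rather than
imputed.

**Gravity removal.** A resting accelerometer reads 1 g. The quasi-static
gravity component is removed with a Butterworth high-pass filter,
cut-off 0.1 Hz. Two decisions were open:

* *Order and phase.* The order is 4, applied forward–backward
  (zero-phase) so that filtering does not shift exercise events in time
  relative to eyes-open/eyes-closed comparisons. This is standard
  biomechanics practice.
* *Edge handling.* A 0.1 Hz high-pass has a multi-second impulse
  response, and naive forward–backward filtering leaves large start-up
  transients on short recordings. The implementation therefore subtracts
  the signal mean (which removes DC exactly) and pads both edges by odd
  reflection (pad length `min(n - 1, 3 * fs / cutoff)`) before
  filtering. The residual edge transient is low-frequency; the band
  features at and above 5 Hz are essentially blind to it. Verified
  against the designed filter's frequency response: the 5 Hz passband
  gain is within 1% of unity in the central part of a recording, and a
  0.01 Hz oscillation is attenuated to the analytic stopband floor
  (~1e-8 in power).

The gyroscope-based orientation-tracking route to gravity rejection is
deliberately out of scope: no concrete algorithm is specified for it in
the source protocol, and the high-pass route is the one demonstrated
there.

## Spectral features

The power spectral density is estimated by Welch's method: segments of
`window_length = 256` samples, overlap fraction 0.5, each segment
mean-detrended and tapered with a periodic Hann window; the averaged
squared spectra are scaled to a one-sided density (units²/Hz), so that
`sum(power) * Δf` equals the signal variance (checked to 5% on white
noise). "Modified periodogram" does not pin down the taper; Hann with
per-segment mean detrending is the common default and is what the 5%
Parseval check assumes.

The features are cumulative high-band sums
`PSD_fx = Σ_{n = idx(fx)}^{N} PSD[n]` — all spectral power at and above
the cut-off — at cut-offs 5, 10 and 15 Hz (configurable). They are
nested by construction (`PSD_5Hz ≥ PSD_10Hz ≥ PSD_15Hz`), which the test
suite asserts as an invariant on random signals. A cut-off above the
Nyquist frequency selects no bins and yields 0 with a warning rather
than an error, since it is a legitimate (if useless) configuration.

For exercises performed both eyes-open and eyes-closed (Romberg,
finger–nose, heel–knee), contrast features compare the two conditions.
The default mode is the ratio `open / closed` with an epsilon guard of
1e-12 on the denominator; a difference mode is available. The ratio was
chosen as the default because the published feature table contains
values clustered tightly around 1.0, the signature of a ratio-style
quantity.

Hand/foot aggregation is not specified anywhere; the package computes
features per sensor and, by default, averages the left/right pair
(`aggregate = "side_mean"`), since published feature values are single
scalars per subject. `aggregate = "per_sensor"` exposes both sides.

## KDE augmentation

With only 23 labelled subjects, classifiers overfit. The cohort is
expanded by fitting a Gaussian kernel density estimate *separately per
class* (preserving label-conditional structure) and drawing synthetic
feature vectors: a uniformly chosen training point plus Gaussian noise
scaled by the bandwidth. Features are standardized to zero mean / unit
variance before fitting and mapped back after sampling, so a single
bandwidth rule (Scott's, `n^(-1/(d+4))`) works across features whose
scales differ by orders of magnitude. Defaults draw 200 negative and 200
positive rows, growing 23 subjects to 423 training rows. Original rows
pass through bit-identical and every row is flagged by provenance.
Synthesis happens in feature space, after extraction — augmenting raw
signals is out of scope.

## Classification and aggregation

**Feature selection.** One-by-one elimination: repeatedly drop the
feature with the largest pooled two-sample t-test p-value until all
retained features have p ≤ 0.05; then, among retained pairs with
|Pearson r| > 0.9, keep the member with the smaller p, so near-duplicate
features never enter a model together. Ties on p are broken by the
larger mean absolute inter-feature correlation, then by reverse
alphabetical order — the procedure is fully deterministic.

**Per-exercise models.** One classifier per exercise, tuned by
stratified 3-fold cross-validated accuracy over a grid: SVM over kernel
{linear, radial, polynomial} × cost {0.1, 1, 10}; ridge logistic
regression over penalty strength; decision tree over maximum depth. The
first best grid point wins ties, so a fixed seed reproduces the chosen
hyperparameters exactly. Every model emits a positive-class probability
(Platt-scaled for the SVM).

**Aggregation.** The screening probability is the arithmetic mean of the
six per-exercise probabilities, thresholded at 0.5. The source formula
is written with a sum from 0 to 6 but a 1/6 factor over six per-exercise
models; the package resolves this index/count mismatch as the arithmetic
mean of exactly six outputs. A missing exercise is a hard error by
default — silently renormalizing would change the operating point — but
`renormalize = TRUE` is available for home-use robustness.

**Split.** Train/test splits are stratified by label and provenance
(largest-remainder allocation), so the train size is exactly
`round(0.7 * n)` — 423 rows split 296/127 — and original pilot subjects
appear on the test side in proportion to their share. Whether the
original 23 belonged only to training was not documented; proportional
stratification is the neutral choice.

## Companion statistics

The group t-test is the *pooled-variance* (Student) form, callable from
raw samples or directly from published mean/SD/n summaries. The pooled
form was chosen because the published age comparison (63.8 ± 8.5, n = 8
vs 50.7 ± 12.0, n = 15, p = 0.012) is reproduced by the pooled test
(p = 0.0125) but not by Welch's (p ≈ 0.007). No multiple-testing
correction is applied, matching the source analysis (`p.adjust` is a
one-liner away for users who want Benjamini–Hochberg). The correlation
matrix of EDx parameters against features uses pairwise-complete
Pearson correlations, reports the point-biserial correlation with the
binary label in a `DMN` column, and masks cells with |r| < 0.100 —
printed and exported as empty fields, mirroring the published
convention. Mann–Whitney U is provided as the nonparametric fallback
with the normal approximation and tie correction.

## The synthetic-data generator

The original patient data are withheld, so the generator is a
first-class module, not a test fixture.

**Feature-level cohorts** draw per-group Gaussians from templates
defaulting to the published group means ± SDs of the 24 anonymized
features (with the 12 most discriminative flagged). Gaussian marginals
are the only defensible choice when only mean ± SD are published.
Truncation at physical bounds is *available* (per-template `lower`
bounds, enforced by rejection) but off by default: truncating e.g.
N(0.005, 0.003) at zero shifts its mean by ≈ +0.0003, which would break
the generator's contract of reproducing the template moments.

**EDx parameters** are generated jointly with features through a shared
latent Gaussian: a parameter with target correlations `ρ_j` to features
`j` is `Σ ρ_j z_j + sqrt(1 − Σ ρ_j²) ε` on the standardized scale.
Infeasible targets (Σ ρ_j² ≥ 1) are rejected with an error naming the
parameter. Targets are defined *within group*: the published pooled
correlations mix within-group association with between-group mean
shifts, and at least one published cell (a positive latency–feature
correlation whose group means move in opposite directions) cannot be a
within-group effect and a pooled effect simultaneously. The EDx group
means/SDs themselves were never published; the defaults are
physiologically plausible synthetic values and are documented as such.

**Signal-level recordings** use the model: 1 g gravity on the vertical
axis + low-frequency sway (0.3–2 Hz) + a tremor oscillation (4–12 Hz) +
white noise, plus a 1.8 Hz Gaussian step-impulse train for the walking
exercises. Severity ∈ [0, 1] scales tremor amplitude up (factor
0.2 + 1.8·severity) and step amplitude down (factor 1 − 0.6·severity),
matching the clinical directions (tremor more expressed, foot strength
reduced); the eyes-closed condition amplifies sway and tremor in
proportion to severity (impaired deep sensibility shows when vision is
removed). All generators are pure functions of their spec including the
seed.

**What passing tests do and do not show.** The generator plants
independent Gaussian features at the published effect sizes; real
movement features are correlated within subject, non-Gaussian, and
contaminated by artifacts. Because the planted group differences
compound independently across six exercises, the synthetic screening
task is *easier* than the clinical one: the simulated ensemble operates
near-perfectly (sensitivity/specificity ≈ 0.97 at 100 subjects/group),
comfortably above the clinically reported operating point
(0.78/0.87/82.1%), which should therefore be read as a lower bound the
synthetic protocol must clear, not a value it estimates. An optional
shared subject-level latent factor (`subject_latent_sd`) is available to
induce cross-exercise correlation; it is off by default because the true
within-subject correlation is unknown.

## Problem sizes and runtime choices

The Monte-Carlo summaries use 100 subjects per group, 200 + 200
augmentation, and 20 seeds (`summarize_experiments()`); this keeps the
full protocol under a minute on one CPU while the binomial error on a
mean rate over 20 × 180 test rows is below one percentage point.
Property-style tests use 1000 random signals (band monotonicity), 10^5
KDE draws (moment recovery), 1000 null replicates (t-test type-I error)
and n = 2000 per group (correlation recovery), each sized so that a
3-standard-error band is decisive.

## Known limitations

* The proprietary definitions of the 24 published features are not
  public; the package implements the disclosed PSD band family plus
  configurable contrasts, and the generator works from the published
  summary statistics, not from reconstructed definitions.
* The published real-data metrics table and correlation matrix cannot be
  reproduced — the patient data are withheld; everything quantitative
  here is computed on synthetic cohorts.
* Gravity rejection uses the high-pass route only; orientation tracking
  from the gyroscope (with drift compensation) is not implemented.
* Zero-phase filtering leaves an edge transient of a few seconds on each
  end of a recording; band features ≥ 5 Hz are insensitive to it, but
  sub-hertz sway analyses on recordings shorter than ~10 s would not be.
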