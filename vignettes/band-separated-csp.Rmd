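---
title: "Band-separated CSP classification of feedback-locked ERPs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Band-separated CSP classification of feedback-locked ERPs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erpcsp)
```

## The scientific problem

Feedback-locked EEG activity in the 200-300 ms window after reward or
punishment mixes at least two functionally distinct components: a
fronto-central theta-band deflection (the reward positivity, RewP, after
positive feedback; the feedback-related negativity, FRN, after negative
feedback) and a slower, centro-parietal delta-band positivity associated
with the P3. Because the two overlap in time with opposite signs, the raw
ERP amplitude at a single electrode confounds them: a more negative FRN can
reflect stronger theta, weaker delta, or both.

`erpcsp` implements a decoding approach to this problem. Subject-level
feedback-locked ERPs are separated into delta and theta components with
sharp zero-phase FIR filters, reduced to the 200-300 ms window, spatially
filtered with Common Spatial Patterns (CSP), and used to classify
symptom-defined groups (elevated depression or anxiety scores vs controls),
one model per frequency band x feedback valence x contrast. Reward- and
punishment-based models are then compared directly with a corrected
resampled t-test. The package also ships a synthetic-EEG generator that
plants band-limited, spatially localized group effects, so the entire chain
is testable against known ground truth.

## Group definitions

Subjects are assigned from two questionnaire totals: the Beck Depression
Inventory-II (BDI-II, 0-63, clinical cutoff 13) and the trait scale of the
State-Trait Anxiety Inventory (STAI-T, 20-80, cutoff around 41). With the
default cutoffs:

* `DEP`: BDI-II > 13 and STAI-T > 41;
* `CTR_DEP`: BDI-II <= 13 and 41 < STAI-T <= 42;
* `ANX`: BDI-II <= 13 and STAI-T > 42;
* `CTR_ANX`: BDI-II <= 13 and STAI-T < 41;
* everyone else (including scores exactly on a cutoff, since all
  comparisons are strict) is `UNASSIGNED`.

The depression contrast keeps anxiety high in *both* classes (controls are
the whole low-BDI/high-STAI cell, `CTR_DEP` plus `ANX`), isolating the
depression dimension as far as a comorbid sample allows. The anxiety
contrast is `ANX` vs `CTR_ANX`. The two contrasts use high-anxiety cutoff
conventions that differ by one point (41 vs 42), so the low-BDI/high-STAI
cell is claimed by both a control group and a symptomatic group; we resolve
this with a fourth configurable cutoff (`stai_anx`, default 42) that splits
the cell, reproducing both group definitions and their partial overlap
while still giving every subject exactly one label. All four cutoffs are
arguments of `assign_groups()`, so either convention can be applied
exactly.

## Band separation

Two windowed-sinc (Hamming) FIR designs separate the bands
(`delta_filter_spec()`, `theta_filter_spec()`, both at 256 Hz):

* delta: lowpass, passband edge 3 Hz, transition bandwidth 2 Hz, so the
  -6 dB (half-amplitude) point sits at 4.00 Hz;
* theta: bandpass 4-7.5 Hz, 2 Hz transitions, -6 dB points at 3.00 and
  8.50 Hz.

Delta-isolation filters of this shape are sometimes mislabeled as
"high-pass at 3 Hz" in EEG-toolbox logs even when the underlying design is
a low-pass; only the low-pass reading (non-causal windowed design, -6 dB
at 4 Hz) isolates delta, and that is what `delta_filter_spec()` encodes.

Kernel length starts at the classical Hamming design heuristic of
3.3/transition-bandwidth seconds, rounded up to an odd tap count, and is
then grown two taps at a time until the *measured* magnitude response meets
the design's rated characteristics: passband ripple at most 0.0194 and at
least 53 dB attenuation everywhere beyond the transition band. This
design-to-spec step matters: the bare heuristic length (423 taps at 256 Hz)
leaves the first stopband lobe at only about 50.5 dB, short of the rating.
The final designs (431 taps for delta, 439 for theta) meet it with exact
-6 dB points; `describe_filters()` prints the measured audit:

```{r}
describe_filters(256)
```

Filters are applied zero-phase: the symmetric kernel is convolved with the
full-length ERP after reflect-padding by half the kernel length (not
forward-backward IIR filtering, which would square the magnitude
response). Filtering always happens on the full epoch *before* the
200-300 ms window is cut, so filter edge transients never reach the
analysis window, and each `subject_erp` records its band so a second
filtering pass is refused.

Milliseconds map to samples by `round((t - t0) * srate / 1000)` with
half-open windows `[start, end)`; at 256 Hz with epochs from -1000 ms the
200-300 ms window is exactly 26 samples. Baseline correction subtracts the
per-channel (per-trial) mean of the -250 to 0 ms interval and is
idempotent. Condition averages require at least five artifact-free trials
per valence, the usual exclusion threshold for feedback ERPs; subjects
below it raise a typed condition (`erpcsp_excluded`) rather than silently
propagating thin averages.

## CSP on subject-level ERPs

Each subject contributes one windowed, band-filtered channels x samples
matrix per valence (about 26 samples of 64 channels). Its spatial
covariance is the raw second moment `X X'` (no demeaning: the deterministic
ERP waveform *is* the signal), trace-normalized to remove inter-subject
amplitude scale, and shrunk towards the scaled identity with weight
`lambda`:

```
C = (1 - lambda) * XX'/tr(XX') + lambda * I/d .
```

Trace normalization means CSP discriminates on the spatial *distribution*
of band power, not its absolute level; shrinkage is numerically mandatory
because 26 samples cannot support a full-rank 64-channel covariance (the
hyperparameter grid therefore never goes below `lambda = 1e-3`).

`csp_fit()` averages the class covariances and solves
`C1 w = mu (C1 + C2) w` by symmetric whitening of `C1 + C2` followed by an
eigendecomposition — numerically stable and exactly equivalent to the
generalized problem for positive-definite sums. Eigenvalues `mu` in [0, 1]
are each filter's share of class-1 variance; 0.5 is uninformative.

Components are selected in interleaved pairs from the two ends of the
eigenvalue spectrum, starting from the end with the larger `|mu - 0.5|`
(ties towards the larger `mu`). This was a genuinely open design point, and
the one-sided alternative (pure `|mu - 0.5|` ranking) fails in an
instructive way: a strong effect concentrated in one spatial direction
inflates that direction's relative variance and thereby *depresses every
other* normalized eigenvalue below 0.5, so the top-m list can come entirely
from one end. Because the classifier sees normalized log-variance features

```
f_j = log( v_j / sum_k v_k ),   v_j = mean((w_j' X)^2),  k over selected,
```

components drawn from a single end rise and fall together across subjects
and cancel in the ratio — we observed chance-level models on synthetic data
with a planted effect whose top eigenvalue was 0.84. Interleaving both ends
guarantees the features encode a contrast between class-favoring
directions. With `m = 1` the normalized feature is identically zero by
construction; such grid points behave as chance models and are only
selected when nothing better exists.

Spatial *patterns* (the forward model used for topographic interpretation,
as opposed to the extraction filters) are recovered through the duality
`A = (C1 + C2) W' (W (C1 + C2) W')^{-1}` and exported per channel with
head-plane coordinates for plotting (`export_patterns()`).

## Classification and inference

The classifier is a support vector machine (`e1071::svm`) over the grid:
CSP components 1-4, `lambda` in [1e-3, 1e-1] (log-spaced), kernel linear or
radial, cost `C` in [1e-5, 1e1] (log-spaced). The radial kernel's bandwidth
is the solver's default (`gamma = 1/n_features`), recorded with the model.
Features are standardized with training-fold statistics only.

* **Selection.** Stratified 3-fold CV; for every grid point the *full*
  pipeline — class covariance averaging, CSP eigendecomposition, SVM and
  its feature scaling — is refit on each training fold, so no test-fold
  subject ever influences any fitted quantity. The winner maximizes mean
  CV balanced accuracy; ties break towards fewer components, then smaller
  cost, then the linear kernel.
* **Scoring.** The selected configuration is evaluated under 10-repeated
  stratified 10-fold CV (100 refits), retaining per-split balanced
  accuracy, ROC AUC (Mann-Whitney with midranks), precision and recall of
  the symptomatic class. The split sequence is a pure function of the
  labels and a seed derived from (master seed, contrast) — *not* from the
  band or valence — so any two models on the same contrast see identical
  splits, which is the paired design the corrected t-test requires.
  A "train ACC" (fit and score on all subjects) is reported as the
  overfitting gauge.
* **Significance.** A permutation test re-runs the entire selection stage
  (same folds) under `B` label permutations, with
  `p = (1 + #{perm >= obs}) / (B + 1)` — valid by construction. `B`
  defaults to 999, giving 0.001 resolution; desk-scale checks use smaller
  `B`.
* **Model comparison.** Reward- vs punishment-based models are compared on
  their paired 100-score vectors with the Nadeau-Bengio corrected
  resampled t-test: `t = mean(d) / sqrt((1/n + rho) var(d))` with
  `rho = n_test/n_train = 1/(k-1)`, df `= n - 1`. With `rho = 0` it reduces
  to the classical paired t-test and is strictly more conservative
  otherwise; degenerate zero-variance differences are reported explicitly
  (`t = 0, p = 1` if the means agree, infinite `t` with a flag otherwise).

The ERP-feature models (`component = "erp"`) use the single classical
RewP/FRN quantification — mean 200-300 ms amplitude at FCz — fed to the
same classifier grid with the CSP stages skipped, providing the
single-electrode baseline the spatially filtered models are measured
against.

## The synthetic generator

`generate_dataset()` emulates a typical feedback-task recording: 64
channels (10-10 cap) at 256 Hz, epochs -1000 to 2400 ms around feedback
onset, 83 positive and 121 negative trials per subject (average
artifact-free counts for speeded tasks with RT-adaptive feedback), two
groups whose questionnaire scores are drawn from truncated normals with
means/SDs representative of questionnaire-defined symptom groups in
community samples, so that `assign_groups()` recovers the planted design
exactly.

Each trial is the sum of:

* a deterministic per-valence ERP template (a fronto-central theta-range
  deflection around 250 ms and a slower centro-parietal positivity),
  common to both groups;
* the planted effects: unit-norm topography x Hann-enveloped cosine at the
  band's center frequency (1.5 Hz delta / 5.75 Hz theta), with source
  amplitude `base + shift * symptomatic + N(0, subject_sd)` per subject
  plus `N(0, trial_sd)` per trial. The default 1400 ms envelope keeps the
  pulse's spectral main lobe within about +-1.4 Hz of the carrier, which
  is what makes a delta-only effect invisible to the theta filter (and
  vice versa) — shorter pulses leak across the 3-4 Hz crossover;
* spatially correlated 1/f background noise: independent unit-variance
  `1/f^alpha` sources (spectral shaping on a power-of-two FFT grid) mixed
  into channels by spatially smoothed random unit-norm loadings, scaled to
  `noise_sd` microvolts per channel. The smooth mixing gives neighboring
  channels correlated noise, which is what makes CSP's spatial filtering
  non-trivial.

What the generator does *not* emulate: volume conduction from a realistic
head model, ocular/muscle artifacts, non-stationary noise, latency jitter
of components across trials and subjects, and any coupling between symptom
severity and signal beyond the planted mean shift. Passing recovery tests
on this test bed therefore demonstrates that the pipeline's statistics and
spatial filtering behave as designed — not that real recordings carry
decodable group differences.

`planted_effect_report()` exposes the ground truth as a table so tests can
decide which model *should* win before anything is fit.

## Numerical choices and degenerate inputs

* Filter response measurement: direct DTFT on a 0.01 Hz grid with linear
  interpolation of the half-amplitude crossing.
* Whitening guards eigenvalues at `eps * max(ev)`; CSP eigenvalues are
  clipped to [0, 1].
* Zero-variance windows raise errors rather than NaN features; precision
  is defined as 0 (flagged) when no positive predictions exist.
* If the smaller class has fewer subjects than `k`, folds are reduced to
  the class size with a warning that is recorded in the CV report.
* Boundary questionnaire scores (exactly at a cutoff) are `UNASSIGNED` by
  the strict inequalities; missing scores warn and stay `UNASSIGNED`.
* All randomness flows from explicit seeds: the master seed fans out to
  generator, fold and permutation streams via a fixed integer hash, and
  every report records the seeds that produced it. RNG state of the
  calling session is saved and restored around every seeded computation.

## Problem sizes used in the validation suite

The test suite validates the pipeline on reduced but structurally faithful
problems, chosen once as realistic for a desk-scale simulation study:
parameter-recovery runs use 40 subjects per group, 16 trials per valence
and the full 64-channel montage with an effect amplitude of 1.5x the
per-channel trial-noise SD; the permutation-calibration study uses 200
zero-effect datasets of 30 subjects per group on an 8-channel midline
montage with 99 permutations each; the leakage study uses 30 subjects per
group. Fewer trials than the emulated recording's average mainly raises
subject-level ERP noise, which the planted effect sizes already dominate.

## Known limitations

* Subject-level (one covariance per subject from a 26-sample window) CSP
  is far from the asymptotic regime; shrinkage and the interleaved
  component rule are load-bearing, not cosmetic.
* The `m = 1` grid point is uninformative under ratio-normalized features
  (see above); it is retained for fidelity to the 1-4 component grid.
* EDF/BDF import returns the continuous recording; epoch segmentation from
  event markers is the caller's responsibility — the package's native
  epoch interchange format is the JSON + float64 container, which
  round-trips bit-exactly.
* The pipeline starts from cleaned epochs. Re-referencing, ocular
  correction and artifact rejection are upstream concerns and out of
  scope.
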