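---
title: "Methods: feature selection and dimensionality reduction for multi-channel sEMG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: feature selection and dimensionality reduction for multi-channel sEMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Myoelectric control decodes movement intent from surface electromyography
(sEMG): multi-channel voltage recorded over contracting forearm muscles,
here at 2 kHz.  The classification pipeline this package implements is the
standard one for hand/wrist movement recognition: denoise, cut the signal
into short overlapping windows, compute a large catalog of per-window
per-channel statistics ("features"), and feed them to a classifier.  Because
many catalog features are redundant (several are exact duplicates or scalar
multiples of one another), the package's focus is the *selection* stage:
which features, and how few dimensions, suffice?

Six routes are implemented under one interface — PCA, LDA, probabilistic PCA
(PPCA), a Gaussian process latent variable model (GPLVM), ReliefF and
L1-penalised logistic regression (Lasso) — plus the brute-force alternative,
exhaustive evaluation of every k-feature subset with the downstream
classifier.

# The synthetic world

Everything is exercised on a seeded generator (`synth_config()`,
`generate_recording()`) that emulates the acquisition protocol of a typical
sEMG session: 6 movement classes, repetitions of 5 s separated by 3 s of
rest, 10–12 channels at 2 kHz.

The signal model per channel is

    x_c(t) = baseline_sd * n_c(t) + gain[m, c] * env(t) * s_c(t) + A * sin(2*pi*50*t)

where `n_c` and `s_c` are independent unit-variance Gaussian noises
band-limited to 20–450 Hz (sEMG is well modelled as a band-limited
stochastic process, and the catalog features respond to exactly the
amplitude and spectral modulation this produces), `env` is a trapezoidal
envelope with 0.5 s linear ramps (avoiding onset discontinuities that would
make difference-based features degenerate), and the optional 50 Hz term is
powerline interference for exercising the notch filter.

Class identity is *amplitude-coded*: the `gain` matrix gives each movement
two dominant channels (gain 3) assigned cyclically, and a deterministic
0.5–1 background on the remaining channels.  The background pattern uses
coprime strides over movements and channels so that every movement's
amplitude profile is unique even on small channel counts (with a naive
cyclic pattern, 6 movements on 6 channels would alias pairwise and the
classes would genuinely collapse — an early version of the generator did
exactly that).  Defaults: `baseline_sd = 0.2` (a strong-contraction SNR of
roughly 20 dB, realistic for forearm extensors), `powerline_amp = 0`.

What the generator does **not** emulate: motor-unit physiology, electrode
lift/shift artifacts, force-level variation, inter-subject anatomical
variability, label noise.  A green test therefore establishes that the
pipeline's *mechanics* are correct and that its statistical behaviour
(chance level on permuted labels, monotone response to class contrast,
redundancy-driven LDA failure) matches construction — not that real-data
accuracy figures are reproduced.  Real-recording accuracies depend on the
actual datasets and are out of scope.

# Preprocessing

A second-order IIR notch at 50 Hz (quality factor 30, i.e. ~1.7 Hz wide —
a standard narrow powerline notch; acquisition protocols rarely state a
width) and a 4th-order
Butterworth bandpass prototype at 20–500 Hz.  No DSP package ships in the
supported environment, so the design chain (analog Butterworth prototype,
zero-pole-gain band transform, bilinear transform) is implemented in the
package and was verified coefficient-for-coefficient against
`scipy.signal.butter`/`iirnotch` during development.

Both filters are applied zero-phase (forward–backward with odd-extension
padding and steady-state initial conditions).  Feature extraction here is
offline, and phase distortion would shift zero-crossing and slope-sign
counts; acquisition protocols rarely state phase handling, so the choice
is recorded here.  One consequence worth knowing: a *narrow* notch has a long
impulse response, so on short tones the edge transient dominates a
whole-signal RMS ratio; gain claims are therefore always measured in the
steady-state region.

Segmentation cuts 250 ms windows with 50% overlap, *only inside annotated
movement intervals* (rest is not one of the classes, so rest windows would
be unlabelable).  Windows never cross interval boundaries.  Sample
coordinates are 0-based half-open throughout.  An interval of `T` samples
yields `floor((T - W)/step) + 1` windows; a 5 s repetition at 2 kHz gives
39.

# The feature catalog

41 features: 35 time-domain, 6 spectral (`feature_catalog()`).  The field's
feature tables name these without printing equations, so the package pins
one standard convention per feature (the formulas are in
`?compute_feature`) and tests each against an independent naive loop
implementation.  Decisions a user should know:

* Thresholded counts (`ZC`, `SSC`, `WAMP`) use window-relative thresholds
  because signal units are arbitrary.  At a zero threshold, `SSC` requires a
  strictly positive slope product and `WAMP` a strictly exceeding
  difference: otherwise a constant window would count every interior sample,
  which contradicts the intent of the statistics.
* Guarded logarithms/divisions (`LD`, `LDAMV`, `LCOV`, `CV`, `MFL`,
  `HMOB`): a `1e-12` floor replaces the offending denominator or log
  argument, so every feature is finite on every window — degenerate windows
  produce guarded values, never `NaN`.
* Spectral features use the one-sided periodogram of the raw window (no
  sub-window averaging: at 500 samples, Welch averaging would cost more
  resolution than it buys), restricted to the 20–500 Hz analysis band; the
  frequency-ratio boundary defaults to 250 Hz.
* Fisher skewness and *excess* kurtosis; natural log for `LDAMV`/`LCOV`,
  `log10` for `MFL` (the convention of the fractal-length literature);
  V-order uses `v = 3` (with `v = 2` it would duplicate RMS); cardinality
  quantizes at `0.01` SD; approximate entropy uses `m = 2`, `r = 0.2` SD.
* `MAV` is appended as feature 41: the classic 40-entry feature tables of
  this literature omit it while the accompanying retained-feature lists
  use it, and without it the 16-feature preset would not be
  constructible.

The exact duplicates in the catalog (`IAV` = `IEMG`, `AAC` = `DAMV`, and
scalar multiples like `MAV` = `IEMG`/N) are kept deliberately: the
downstream behaviour of redundant features — identical rankings, singular
LDA scatter — is part of what the pipeline is meant to exhibit.

# Classifier and cross-validation

A feed-forward network with three hidden layers of 20 ReLU units and a
softmax output, trained with Adam (learning rate 1e-3, batch
`min(n, 128)`) for a fixed number of epochs — 1000 in the `paper` profile (the reference protocol this package
reproduces), with no early stopping so the iteration budget is honoured
exactly; 150 in the
`fast` profile used for desk-scale runs where thousands of trainings are
needed (exhaustive search).  The optimizer settings are package decisions —
reference protocols for this pipeline state only architecture, activation
and iteration count — and "three-layer" is read as three *hidden* layers.  Training is implemented in
compiled code and is bit-deterministic for a fixed seed.

Evaluation is stratified 5-fold cross-validation.  The z-scaler and any
reduction method are fit inside each training fold only; the no-leakage
contract is tested by checking that permuting held-out-fold labels leaves
training-fold weights bit-identical.  When many models must be comparable
(ranking, subset search) one fold assignment is computed once and shared.

# Ranking and elimination

Each feature is scored alone: its per-channel columns form an
n_channels-dimensional input, and the cross-validated accuracy becomes the
feature's score.  Features below the threshold are eliminated.  The default
threshold is 0.85 — the value applied in the elimination step of the
protocol this package reproduces — while the 0.80 screening value quoted
alongside it is equally supported; both are recorded in reports because
the two stated values genuinely conflict.  `paper16_features()` ships the canonical 16-feature retained set of that
protocol (its prose lists 14 names; RMS and LD are recovered from its
top-subset tables) so downstream stages can run without re-ranking.

# Reduction methods

All six methods expose `transform()` for new rows and are fit per training
fold inside `evaluate_reduction()`.

* **PCA**: SVD of the centered matrix; default dimension = components
  covering 95% variance (a package default; retained dimensions are
  rarely reported).
* **LDA**: generalized eigenvectors of between/within scatter, bounded by
  `n_classes - 1` dimensions.  A within-scatter condition number above 1e12
  raises `emg_singular_scatter_error` naming the collinear columns found by
  pivoted QR.  This is deliberate: with exact duplicates in the retained
  catalog the scatter *is* singular, and reporting it reproduces the known
  failure mode of LDA on redundant sEMG feature sets.  No automatic shrinkage; a
  `ridge` argument exists for users who want it anyway.
* **PPCA**: Tipping–Bishop EM with Woodbury-form likelihood; the trace is
  non-decreasing (asserted to 1e-9), convergence at `dll < 1e-6`.
  Dimension default mirrors PCA's 95% rule.
* **GPLVM**: RBF (or linear) kernel plus white noise; latent coordinates
  and hyperparameters jointly optimized by gradient descent with a
  backtracking line search from PCA initialisation, so the accepted-step
  objective trace is non-increasing by construction.  These are MAP point
  estimates, not Bayesian inference over the mapping.  Dense kernel algebra
  is O(n^3), so fits beyond 3000 rows must opt into `subsample`; fold-wise
  fits inside `evaluate_reduction()` subsample to 300 rows.  Out-of-sample
  rows are mapped by a ridge regression from data space onto the optimized
  latents — the model has no parametric inverse map, and the linear
  back-projection keeps the transform deterministic and cheap.  Default
  `d = 10`.
* **ReliefF**: multiclass nearest-hit/nearest-miss weighting (Manhattan
  distances on z-scored inputs, miss terms weighted by class prior,
  range-normalised differences), `k = 10` neighbours, top 25% of columns
  selected by default.
* **Lasso**: one-vs-rest L1-penalised logistic regressions (via glmnet)
  over a shared penalty grid; the penalty is chosen by cross-validated
  accuracy of the argmax linear scores, ties resolved toward the sparser
  model.  One-vs-rest rather than multinomial is a package decision and is
  flagged as such.  An empty selection at the chosen
  penalty falls back to the smallest penalty with a warning.

Wall-clock seconds are recorded in comparison tables because computational
cost is half of the comparison's point, but no test or acceptance check
asserts on them — they are hardware-dependent.

# Exhaustive subset search

`enumerate_subsets()` lists all `choose(n, k)` k-subsets in lexicographic
order; `exhaustive_search()` evaluates each subset's features (all channels
of each chosen feature, consistent with the ranking input convention) under
one shared fold assignment, and reports the sorted table, the top 10 and
the accuracy range.  Ties in the top-10 are broken by lexicographic subset
order (an arbitrary but fixed convention).  A JSON-lines checkpoint makes long searches
resumable with an identical final report.  For 16 retained features the
k = 2..5 searches are 120, 560, 1820 and 4368 evaluations — the reason the
`fast` profile exists.

`compare_set_sizes()` takes each size's top-10 accuracies as its replicate
group — comparisons of "top 10 sets" across sizes need a replicate unit,
and the top-10 accuracy vector is this package's rendering — and runs the one-way ANOVA, flagging whether mean accuracy is
non-decreasing in k.

One behaviour worth stating plainly: at the generator's default
signal-to-noise ratio the classes are fully separable, top subsets of every
size reach accuracy 1.0, and the "accuracy grows with set size" trend holds
as a chain of equalities at the ceiling.  A genuinely increasing trend
appears once `baseline_sd` is raised enough to create headroom (at
`baseline_sd = 4`, for example, top-10 means rise from ~0.93 at k = 2 to
~0.95 at k = 5), but there the per-seed ordering of adjacent sizes becomes
noisy — strict per-seed monotonicity is only a reliable property of the
stated default world, which is what the tests assert on.

# Numerical and degenerate-input policy

* Identical seeds give bit-identical generators, fold assignments, network
  weights and reports.
* Seeds derived internally stay below 2^31.
* Empty annotation tables segment to empty sets (not errors); an interval
  shorter than one window is skipped with a warning; an empty retained set
  raises an explicit error.
* The F statistic with zero between- *and* within-group variance is
  reported as F = 0, p = 1 (identical groups are evidence of no
  difference); zero within-group variance with nonzero between-group
  variance is an error, since F is undefined.

# Known limitations

* The ANN is a fixed architecture; no hyperparameter search (out of scope).
* GPLVM out-of-sample mapping is linear; a test row far from the training
  manifold maps poorly.  Inducing-point sparse GPLVMs are not implemented.
* ReliefF is O(n^2) in rows; fine at desk scale, slow beyond ~5k windows.
* The synthetic world is amplitude-coded; spectral-shape-coded classes
  (e.g. fatigue studies) would exercise different catalog features.
* Real-dataset ingestion (the MAT-based layouts of the public sEMG
  databases) is not implemented; the TSV + JSON sidecar reader is the
  supported input path.
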