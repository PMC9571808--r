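---
title: "Methods: virtual electronic nose analysis of temperature-cycled sensor signals"
author: "venose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: virtual electronic nose analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
decisions behind the package, and what the simulation-based tests do and
do not establish about real sensor data.

## The measurement model

A single field-effect gas sensor is driven through a repeating
temperature program: five plateaus from 360 °C down to 240 °C in 30 °C
steps, each held for 22 s, sampled at 10 Hz — 1100 samples per 110 s
cycle, cycles concatenated back to back. Because the surface chemistry at
each plateau differs, each plateau acts as a distinct sensor: the
per-plateau cycle means across consecutive cycles are the five *virtual
sensors* of a one-device array.

The simulator (`simulate_trace()`) generates the drain current as

    I(t) = I0(T_meas(t)) * (1 + s * g(t) * R(gas, T, c) / 100) * d(t) + e(t)

* `I0(T) = i_ref * exp(temp_coef * (T - t_ref))` — a smooth, strictly
  positive baseline (defaults 50 a.u., 0.0025/°C, 300 °C; roughly ±15%
  swing over the cycle).
* `T_meas` lags the set program with a first-order time constant
  `tau_T = 2 s`, so each 22 s plateau settles well within its hold time.
  One unrecorded warm-up cycle is filtered first so acquisition starts in
  the periodic steady state, as on continuously cycled hardware.
* `R(gas, T, c) = A(gas, T) * (c / c_ref)^beta` — a power-law
  (Freundlich-type) isotherm in concentration, `c_ref = 1000 ppb`,
  `beta = 0.7` (sub-linear, consistent with the saturation seen above
  ~2 ppm in this class of sensor). The per-plateau amplitudes `A` keep
  the ordering CH2O > CH2O2 > CH3COOH at every plateau, with
  gas-specific temperature profiles (CH2O peaking hot, CH2O2 mid, acetic
  acid flattest, relatively strongest cold). The profiles differing in
  *shape*, not only magnitude, is what makes the gases distinguishable
  after per-cycle standardization.
* `g(t)` — adsorption/desorption coverage, first-order with
  `tau_gas = 60 s` at gas on/off. Coverage dynamics are deliberately
  separated from the temperature dependence of the amplitude: the
  temperature modulation within a cycle is treated as instantaneous,
  while coverage builds over minutes. (A single lag applied to the
  combined response target would never settle within a 22 s plateau and
  would contradict the plateau-wise steady response the analysis
  assumes.)
* `s = -1` — gas exposure decreases the current by default. The sign is
  configurable (`response_sign`); the relative-response definition takes
  an absolute value, so downstream analysis is indifferent to it.
* `d(t)` — linear drift (0.5 %/h default) plus an optional random walk;
  `e(t)` — Gaussian noise with sd `noise_sd = 0.2%` of the local
  baseline, a realistic magnitude for a lab source-measure setup.

With noise and drift set to zero the preprocessing chain recovers
`R(gas, T, c)` from simulated traces to better than 1e-6 relative error
(test suite), which ties the whole pipeline to the generating formula.

## Study design

`make_study()` follows the three-phase exposure protocol — carrier-gas
baseline, gas exposure, carrier-gas recovery — at desk scale: 10 / 12 / 4
cycles by default. Concentration order is randomized within each gas
block (never a monotone ramp, to avoid confounding with drift and memory
effects), and synthetic air participates as its own class through
all-carrier control exposures.

The `demo` fixture is the full design: 3 VOCs × 7 levels (250–3000 ppb,
evenly spaced) + 7 SA controls, with 8 exposure cycles per exposure.
After discarding the first 2 exposure cycles of each exposure as
settling (`discard = 2`; the 60 s adsorption constant means cycle 1–2 are
still transient), each exposure contributes 6 observations: 42 per gas,
168 in total. The `tiny` fixture (2 gases × 2 levels, short phases) keeps
unit tests fast.

## Preprocessing

The order is smoothing **then** per-cycle standardization (the tests pin
this order down, since reversing it changes the result):

* Savitzky–Golay filter, window 11 samples (1.1 s), polynomial order 3 —
  short enough to preserve the 22 s plateau structure and the plateau-step
  transients, long enough to suppress sample-to-sample noise at 10 Hz.
* Auto-scaling per cycle: `(y - mean) / sd * 100` with the
  (n−1)-denominator sample standard deviation, per cycle (the cycle is
  the natural drift-correction unit; standardizing whole traces would
  leave slow drift inside). Affine invariance makes additive and
  multiplicative drift removal exact; a constant cycle raises an explicit
  degenerate-input error rather than returning NaN.
* Cycle segmentation floors to whole cycles and discards the partial
  tail. Phase tagging is by majority over samples: a cycle is `exposure`
  iff at least half its samples lie in a gas segment; remaining ties
  resolve towards the later phase.
* Virtual sensors use the full plateau window by default
  (`window_fraction = 1`); the last-50% option excludes the thermal
  transient when raw (unsmoothed) traces are used.

## The 299-feature catalog

Per standardized cycle: 55 means over 2 s windows, 220 OLS slopes over
0.5 s windows (in signal units per second; least-squares rather than
endpoint differences, for noise robustness), 22 FFT magnitudes over 5 s
windows, one trapezoidal integral, one lifting. Windows are 0-based,
half-open, contiguous and tile the cycle exactly; counts scale with the
program (the catalog refuses programs whose cycle length the windows do
not divide).

Two conventions the field leaves open are fixed here as configuration
constants: the FFT summary is the magnitude of the **first non-DC** DFT
bin (the DC bin would duplicate the windowed means; `fft_bin` overrides),
and lifting is **last − first** sample (positive = rising cycle).

## Feature selection

`sfs_select()` is plain sequential forward selection: grow the subset one
feature at a time, each step adding the feature that maximizes the
cross-validated criterion of the grown subset; ties break towards the
lowest column index; no backtracking. The criterion is 10-fold CV
accuracy of the chosen SVM for classification tasks and 10-fold CV R² of
PLSR (capped at 3 components) for quantification. The fold assignment is
drawn once per search and reused for every candidate, making the search
deterministic given its seed and keeping candidates comparable. Features
are z-scored inside each training fold only, so no information leaks from
held-out folds. Eight features are selected by default for every task,
and each task (gas identity, per-gas concentration classes, per-gas
calibration) re-runs its own search.

## Model heads

* **LDA** (`lda_fit_project()`): z-scored features projected onto at most
  (classes − 1) discriminant functions for visualization. If the
  within-class scatter is singular or collinear, a shrinkage fallback
  regularizes it towards a scaled identity (weight 0.1) and solves the
  generalized eigenproblem directly; the fallback is announced with a
  message.
* **SVM** (`svm_crossval()`): stratified k-fold CV, out-of-fold
  predictions filling the confusion matrix; quadratic kernel
  (polynomial degree 2, coef0 = 1) by default with a linear option —
  both kernels are in common use for this task and the package exposes
  both. Multi-class is one-vs-one with majority vote (the e1071/libsvm
  standard). For the gas-identity task each gas is one group pooling all
  its concentrations. `svm_crossval()` refuses classes smaller than the
  fold count; since the per-gas concentration task has only ~6 cycles
  per level at this study scale, `venose()` caps that task's fold count
  at the smallest class size and keeps 10-fold for the gas task.
* **PLSR** (`plsr_quantify()`): one 80/20 split, stratified over
  concentration levels when levels are replicated (plain random split
  otherwise), made before any fitting; z-scoring and component choice
  are learned on the training portion only. Components are chosen by
  k-fold CV on the training set with the one-standard-error rule
  (smallest component count within 1 SE of the minimum CV RMSE), which
  guards against overfitting when observations are few. R² and RMSE are
  reported on the held-out test set.

The PLS engine is a compact SIMPLS implementation for a univariate
response (`pls1_fit()`), small enough to sit inside the forward search's
inner CV loop. Its correctness is pinned in the test suite two ways: at
full rank its training predictions equal ordinary least squares, and its
component-wise predictions match the mixOmics reference implementation to
1e-8.

## Numerical and reproducibility choices

* All randomness flows from explicit seeds; child seeds for exposures,
  folds and splits are derived from the master seed, and helpers restore
  the caller's RNG state.
* Z-scoring keeps zero-variance columns at sd 1 (they map to exact
  zeros) rather than producing NaN.
* Metrics: RMSE = root mean squared error; R² = 1 − SS_res/SS_tot, so a
  constant prediction at the mean scores exactly 0 and worse-than-mean
  predictions go negative. R² on a zero-variance truth is an explicit
  error.
* File handoff between pipeline stages rounds through 15-significant-
  digit CSV text; re-running the same stage on the same inputs is
  bit-identical, while in-memory and file-based routes agree to ~1e-9.

## Problem sizes

The shipped analyses are sized for interactive use on one CPU: the demo
study (168 observations × 299 features) fits end to end, including four
forward searches and all model heads, in a few minutes; the
noise-degradation study in the tests uses 12-exposure studies
(36 observations) over a 4-point noise grid × 10 seeds.

## What the simulation does and does not establish

The generator reproduces the statistical structure the analysis relies
on: per-plateau steady responses with gas- and temperature-dependent
amplitudes, sub-linear concentration dependence, slow adsorption
transients, drift and sensor noise, randomized exposure order. Passing
recovery tests on these data therefore validates the *pipeline* — the
preprocessing algebra, the feature definitions, leakage-free selection
and honest validation accounting.

It does not establish field performance of any physical device: the
isotherm is phenomenological (no adsorption-kinetics model of the
catalytic gate), humidity is absent (dry carrier gas only), temperature
control is ideal (no plateau jitter, so no cycle alignment/warping is
implemented), and cross-sensitivities, aging and gas mixtures are out of
scope. Reported accuracies on synthetic data characterize the method
under the simulator's assumptions, not a hardware sensor.
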