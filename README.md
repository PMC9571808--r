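# venose

A virtual electronic nose in R: chemometric analysis of a **single** gas
sensor operated in temperature-cycled (dynamic) mode, so that each
temperature plateau behaves like a distinct sensor of a virtual array.
The package targets the discrimination, classification and quantification
of short-chain oxygenated volatile organic compounds — formaldehyde
(CH2O), formic acid (CH2O2) and acetic acid (CH3COOH) — in the
parts-per-billion range against a synthetic-air (SA) carrier, the setting
of SiC field-effect transistor (SiCFET) gas sensing. A phenomenological
simulator stands in for the hardware and the gas-mixing rig, so the whole
analysis chain can be exercised, tested and benchmarked with known ground
truth.

## Method

The sensor is driven through a repeating temperature cycle (default: five
plateaus from 360 down to 240 °C, 30 °C steps, 22 s per plateau, sampled
at 10 Hz — 1100 points per 110 s cycle). The analysis chain is:

1. **Preprocessing.** Savitzky–Golay smoothing of the current trace, then
   segmentation into cycles, then per-cycle auto-scaling
   `y_std = (y − ȳ) / s(y) × 100` (sample standard deviation), which
   removes additive and multiplicative baseline drift. The *relative
   response* of the sensor is `|I_air − I_gas| / I_air × 100` (%), and
   the per-plateau cycle means form the five **virtual sensors**.
2. **Features.** Per standardized cycle: 55 means (2 s windows),
   220 OLS slopes (0.5 s windows), 22 FFT magnitudes (first non-DC bin of
   5 s windows), the cycle integral and the lifting (last − first
   sample) — **299 features**.
3. **Selection.** Sequential forward selection (SFS) of 8 features,
   scored by 10-fold cross-validated SVM accuracy (classification) or
   PLSR R² (quantification).
4. **Models.** LDA projection for visualization; 10-fold CV SVM
   (quadratic or linear kernel) for gas identity (each gas one group,
   pooling all its concentrations) and for concentration levels within
   each gas; PLSR (SIMPLS) with an 80/20 train/test split and CV-chosen
   components for concentration calibration, reported as RMSE and R².

The simulator generates gas responses from the power-law isotherm
`R(gas, T, c) = A(gas, T) · (c/c_ref)^β` (% of baseline current) with
first-order temperature and adsorption transients, linear/random-walk
drift and Gaussian noise; with noise and drift disabled the preprocessing
chain recovers `R` from simulated traces to 1e-6 relative accuracy, which
is the package's central correctness oracle.

## Worked example

```r
library(venose)

study    <- make_fixtures("demo", seed = 1)   # 3 VOCs + SA, 7 levels, 168 obs
obs      <- study_observations(study, discard = 2)
features <- extract_features(obs)
fit      <- venose(features, k = 8, kernel = "quadratic", folds = 10, seed = 1)
print(fit)
```

```
Virtual electronic nose fit
  168 observations, 8 selected features (mean_23, mean_45, mean_03, slope_001, mean_11, mean_13, slope_132, slope_141)
  gas identity: 10-fold CV quadratic SVM accuracy 95.8%
  CH2O     conc. classification 100.0%, PLSR R2 0.993 (RMSE 74 ppb)
  CH2O2    conc. classification 100.0%, PLSR R2 0.999 (RMSE 30 ppb)
  CH3COOH  conc. classification 97.6%, PLSR R2 0.980 (RMSE 129 ppb)
```

The fit reports out-of-fold (validation) accuracy for the four-class
gas-identity task, per-gas accuracy for classifying the seven
concentration levels (250–3000 ppb), and the held-out test R²/RMSE of the
per-gas PLSR calibration. `summary(fit)` adds the confusion matrix and
per-class rates, `plot(fit)` draws the LDA score scatter, and
`predict(fit, new_features)` returns predicted gas identity and
concentration for new cycles.

The same chain is available as a config-driven pipeline
(`run_pipeline(venose_config(), out_dir)`) that writes every artifact —
trace CSVs, cycle matrices, the feature table, selection and report JSONs
and a Markdown summary — and as a command-line wrapper
(`inst/cli/venose.R`) with `simulate | preprocess | features | select |
classify | quantify | all` subcommands.

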