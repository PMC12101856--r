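---
title: "Quantifying blood hormones from SERS spectra: models and methods"
author: "serscal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying blood hormones from SERS spectra: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serscal)
```

## The problem

Surface-enhanced Raman spectroscopy (SERS) of blood mixed with silver
nanoparticles produces spectra whose band intensities shift subtly with the
concentration of circulating analytes. `serscal` implements a complete
chemometric calibration chain for two such analytes — growth hormone (GH)
and testosterone (TE), both in ng/ml — built around three statistical
components:

1. a **synthetic spectrum generator** that emulates blood-SERS measurements
   with concentration-sensitive bands (no public raw data exist for this
   design, so the generator is a first-class, tested module and defines the
   study conditions used by the test suite);
2. a **calibration model**: vector normalization, principal-component (PC)
   score extraction, and a multilayer perceptron (MLP) trained with
   resilient backpropagation with weight backtracking (Rprop+) that maps
   six PC scores to concentration;
3. **figures of merit**: RMSE and the coefficient of determination on a
   held-out partition, and multivariate limits of detection/quantification
   from blank leverages.

## The spectrum generator

A clean spectrum on the wavenumber grid $\nu$ (default 400–1800 cm$^{-1}$
in 2 cm$^{-1}$ steps) is a sum of unit-height Lorentzian bands plus a
gentle quadratic baseline:

$$ s(\nu) = \sum_b \frac{a_b\,\bigl(1 + g_b f(C_{GH}) + t_b f(C_{TE})\bigr)}
   {1 + \left((\nu - c_b)/w_b\right)^2} + \mathrm{baseline}(\nu), \qquad
   f(C) = \frac{C}{C + K}. $$

* Band centers $c_b$ combine the ten prominent blood bands
  (658–1658 cm$^{-1}$) with the hormone-discriminating bands seen in
  loading analyses: GH-sensitive at 658, 684, 1042, 1378 and 1596
  cm$^{-1}$, TE-sensitive at 798, 912/914, 1240 and 1690 cm$^{-1}$.
  Sensitive bands carry sensitivity $g_b$ or $t_b = 0.6$, all others 0.
  The 912/914 pair describes one physical feature reported at two adjacent
  positions; its amplitude is split between the two rows so the combined
  peak stays at the common band height.
* $f(C) = C/(C+K)$ with $K = 20$ ng/ml is a saturating (adsorption-style)
  response: SERS intensities cannot grow without bound, and the resulting
  nonlinearity is the reason a neural calibration is used instead of a
  linear one. Its derivative falls off as $(C+K)^{-2}$, which concentrates
  the quantification difficulty at the top of the working range.
* Noise: each spectrum is multiplied by a factor $m \sim N(1, 0.05)$
  (collection-efficiency jitter; removed exactly by vector normalization)
  and channel-wise Gaussian noise with SD equal to 1% of the clean
  spectrum's maximum is added. Intensities are clipped at zero.
* Calibration samples are blood matrix spiked with one analyte, so the
  non-varied hormone sits at its endogenous baseline (GH 3, TE 2 ng/ml)
  rather than zero; "blank" spectra are the same matrix with zero analyte.

The default calibration design is 30 log-spaced levels from 0.01 to
60 ng/ml with 30 replicate spectra each (900 spectra), reproducible from a
single seed.

```{r generator, eval = FALSE}
cfg <- generator_config()
cal <- simulate_calibration_set(cfg, "gh", seed = 42)
cal
```

### In-vivo time courses

Injection experiments are emulated with a Bateman (one-compartment,
first-order absorption/elimination) profile
$C(t) = \mathrm{baseline} + A(e^{-k_e t} - e^{-k_a t})$. Given a baseline,
a peak concentration and a peak time, the two rate constants and the
amplitude are solved numerically (root search on the rate ratio) so the
maximum is exact and the concentration has returned to within a few
percent of baseline by 24 h. Defaults: GH baseline 3 ng/ml, peak 44 ng/ml
at 0.5 h; TE baseline 2 ng/ml, peak 30 ng/ml at 2 h (the TE peak height is
a package choice — only its timing window is constrained by the in-vivo
narrative). The four-group experiment (non-injected, GH, TE, GH+TE; six
rats per group; sampling at 0, 0.5, 2, 4, 8, 24 h) draws a lognormal
per-rat peak factor (sdlog 0.1) to emulate between-animal variation.

## Preprocessing and descriptive statistics

Spectra are normalized per replicate and then averaged
(`normalize_spectra()`, `average_spectra()`; the pipeline fixes the order
normalize → average, and the two orders genuinely differ). Vector
(Euclidean) normalization is the default — the most common Raman practice
and the one that exactly cancels per-spectrum multiplicative jitter;
max- and area-normalization are selectable. Band intensities are windowed
maxima (default half-window 10 cm$^{-1}$) because reported band positions
drift by a few cm$^{-1}$ between figures of the same data set. Per-band
group comparisons use the pooled within-group SD/variance and a one-way
fixed-effects ANOVA (via `stats::lm`/`anova`).

## PC scores and the calibration network

`fit_spectral_pca()` is an SVD of the column-mean-centered intensity
matrix (`stats::prcomp`; no channel scaling, since all channels share
units), with a deterministic sign convention (each loading's
largest-magnitude element positive) so serialized models are reproducible.
Six scores feed the regression, mirroring the published architecture
choice; `loading_peaks()` ranks local extrema of a loading to identify the
bands driving separation, breaking ties toward the lower wavenumber.

The two regression networks are ReLU MLPs with a linear output:
6 → 12:10:10:10:6 → 1 for GH and 6 → 10:8:8:8:6 → 1 for TE. Weights start
He-style uniform (fan-in scaled), biases at zero. Training is full-batch
Rprop+ on the mean-squared error: per parameter, the step grows by
$\eta^+ = 1.2$ while the gradient sign is stable (capped at
$\Delta_{max} = 50$) and shrinks by $\eta^- = 0.5$ when it flips
(floored at $\Delta_{min} = 10^{-6}$), in which case the previous update
is reverted and the gradient memory cleared; only gradient signs are ever
used. The initial step is $\Delta_0 = 0.01$, suited to the standardized
inputs.

Two estimator-level choices matter and were made after their naive
alternatives demonstrably failed on the generator's data:

* **Score standardization** uses one common factor (the SD of the first
  PC) rather than per-PC z-scoring. Five of the six scores are
  noise-dominated; z-scoring inflates them to unit variance and the
  network then fits that noise (validation RMSE roughly triples).
* **Stopping** is by cross-validated early stopping, not by training-loss
  plateau: within the training partition, `kfold_cv(trace = TRUE)` records
  the held-fold error per epoch and the final networks are trained for the
  epoch that minimizes its fold-mean. Full-batch Rprop+ run to a plateau
  memorizes spectral noise (the held-out error rises monotonically long
  before the training loss flattens). The plateau rule (tolerance
  $10^{-8}$, patience 50) remains the default for standalone
  `mlp_train()`.
* The final predictor is a **committee of five** independently initialized
  networks whose predictions are averaged, damping the
  initialization-to-initialization variance of individual Rprop+ runs.

Splits are concentration-stratified: the 75/25 hold-out keeps every level
on both sides (900 → 675/225) and `kfold_assign()` deals shuffled
replicates into k = 4 folds with a rotating pointer so fold sizes differ
by at most one.

## Figures of merit

On prediction/actual pairs, `rmse()` is
$\sqrt{N^{-1}\sum_j (P_j - A_j)^2}$ and `r_squared()` is
$1 - \sum_j (A_j - P_j)^2 / \sum_j (A_j - \bar A)^2$ — the regression
definition, which can be negative for bad models and is reported as
computed.

Detection limits follow the multivariate blank-leverage form

$$ \mathrm{LOD} = 3.3\sqrt{\frac{\sigma_b^2}{S_0^2}(1 + h_0) +
   h_0\,\sigma_{ycal}^2}, $$

evaluated at the minimum and maximum leverage
$h_0 = t_0^\top (T^\top T)^{-1} t_0$ of blank spectra projected into the
centered calibration score space; replacing 3.3 by 10 gives the LOQ, so
LOQ/LOD = 10/3.3 exactly. For a nonlinear calibration there is no single
sensitivity $S_0$, so the package uses an operational surrogate:
$\sigma_b/S_0$ is estimated as the SD of the model's *predicted
concentration* over replicate blanks (equivalently $S_0 = 1$ on that
scale), and $\sigma_{ycal}$ is the SD of training residuals in ng/ml.
This surrogate is a documented choice, and both estimators are plain
function arguments that can be swapped.

## ELISA comparison

Standard curves use the two printed functional forms — a Boltzmann sigmoid
$OD(x) = A_2 + (A_1 - A_2)/(1 + e^{(x - x_0)/dx})$ for GH and an
exponential decay $OD(x) = y_0 + A e^{-x/t}$ for TE — fitted by
Levenberg–Marquardt least squares (`minpack.lm::nlsLM`) from a data-driven
start plus two perturbed restarts. Both forms invert in closed form;
inverse prediction is refused outside the OD range spanned by the fitted
standards (extrapolating an immunoassay curve is meaningless) and clipped
at zero. `compare_methods()` joins ANN and ELISA predictions on group and
time and reports paired differences, Pearson correlation and peak-time
agreement.

## Numerical and degenerate-input choices

* All-zero spectra cannot be normalized and raise an error naming the
  offending spectrum id; empty groups, single-group ANOVA, singular
  $T^\top T$ (fewer calibration spectra than components), zero $S_0$ and
  out-of-range band windows are all hard errors rather than warnings.
* Every stochastic stage (simulation, splits, folds, initialization,
  blanks) derives from one integer seed; identical seeds give
  bit-identical spectrum sets and reports.
* Levels with a single replicate go to the training side of a split, with
  a warning.
* `loading_peaks()` ignores zero-magnitude channels; requesting more peaks
  than exist returns all of them, flagged.

## What the generator does and does not emulate

The generator reproduces: band positions and hormone-specific intensity
modulation with saturation, replicate-level instrument noise, per-spectrum
intensity jitter, smooth baseline, realistic calibration and in-vivo
designs, and endogenous hormone backgrounds. It does **not** emulate
correlated (smooth) noise, baseline drift between spectra, cosmic-ray
spikes, matrix effects beyond the two analytes, or any physical
electromagnetic-enhancement modelling of the nanoparticles. Passing tests
therefore demonstrate the correctness and statistical behaviour of the
analysis chain under a known truth — not the field performance of a real
spectrometer.

Two consequences of the chosen noise regime (1% additive channel noise,
5% jitter) are worth stating plainly, because the test suite reports them
honestly:

* With i.i.d. channel noise on ~700 channels and essentially one
  concentration factor per set, the structured fraction of the spectral
  variance is about 70%; six PCs therefore capture ~70% rather than ~90%
  of the total variance. The ~90% figure reported for the real data
  implies additional structured biological/baseline variation that the
  generator deliberately does not invent.
* The per-spectrum information floor for concentration error (matched
  filter on the sensitive bands, error mapped through $f^{-1}$) sits near
  0.6 ng/ml for GH and slightly higher for TE, which has fewer effective
  sensitive bands. The GH validation RMSE lands at that floor; the TE
  network cannot reach the tighter TE bound under these noise conditions,
  and the corresponding acceptance check is expected to fail — by
  construction of the conditions, not by a defect of the estimator.

Problem sizes used throughout the tests are the study conditions
themselves (900-spectrum calibrations, 144-spectrum group experiments);
unit tests use coarser grids and smaller designs where full resolution is
irrelevant to the property under test.

## Known limitations

* Each calibration is single-analyte: a GH model applied to samples in
  which TE varies strongly (TE or GH+TE groups) shows cross-hormone
  aliasing through the normalization coupling. The GH and GH-only group
  predictions are unaffected; multi-analyte calibration would require a
  mixed spiking design, which the published experiment did not include.
* LOD/LOQ depend on the predicted-concentration surrogate for
  $\sigma_b/S_0$; other sensitivity definitions rescale the limits.
* The Rprop+ trainer is full-batch by design; no minibatching, momentum,
  weight decay or architecture search is provided.
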