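---
title: "Methods: rotational hyperspectral calibration modelling in rotospec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rotational hyperspectral calibration modelling in rotospec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

rotospec implements a complete chemometrics workflow for predicting
internal quality traits of fruit — starch (%), vitamin C (per mille),
soluble solids content (SSC, %) and titratable acid (TA, per mille) —
from hyperspectral reflectance images acquired by rotating each fruit
through four 90 degree views. This vignette explains the models and
procedures, the tunable parameters and their defaults, the synthetic
data generator that stands in for instrument data, and the design
choices made where the design was genuinely open.

```{r setup}
library(rotospec)
```

## The measurement model

A push-broom imager records raw counts per pixel and band. Dark-current
and white-reference frames convert counts to relative reflectance,

$$R = \frac{R_\mathrm{origin} - R_\mathrm{dark}}
           {R_\mathrm{white} - R_\mathrm{dark}},$$

implemented element-wise in `reflectance_correct()`. Values outside
[0, 1] are preserved: on specular pixels the formula legitimately
exceeds 1, and clamping would hide exactly the artefact the ROI stage
is meant to reject.

The fruit region of interest is extracted by region growing
(`region_grow_roi()`): starting from a seed point in a clean area, each
round admits the 4-connected frontier pixels whose value lies within
mean ± 2.2 SD of the current region, for at most 50 rounds or until the
region's bounding box reaches 480 x 480 pixels. Three choices here were
open and are fixed as follows:

* the statistic is computed on a **single band image**, by default the
  band nearest 680 nm where pigment contrast is strongest;
* mean and SD are updated **once per round** (batch), so the result
  does not depend on any pixel visiting order;
* the SD is the **region's own** SD, not the global image SD, and the
  seed's 3 x 3 neighbourhood initialises the region so the SD is
  defined from the first round.

The mask's mean spectrum (`mean_roi_spectrum()`) is the sample's
spectrum for that view; the four rotational views are averaged
element-wise (`aggregate_views()`) into one spectrum per fruit. The
acquisition protocol never dictates whether modelling should use 240
per-view spectra or 60 per-sample means; averaging is the default
because the views are exchangeable repeated measurements of one fruit,
and `pipeline_config(aggregate_views = FALSE)` keeps the per-view
alternative.

## Preprocessing registry

Nine transforms (plus the identity, `"Origin"`) live behind
`apply_pipeline()`, all preserving the row and band counts so band
indices stay aligned with the 320-point wavelength grid:

| method | operation | parameters (default) |
|---|---|---|
| SG | Savitzky–Golay smoothing | window 11, polyorder 2 |
| MA | moving average, reflect-padded | window 5 |
| NM | per-row min–max to [0, 1] | — |
| MSC | multiplicative scatter correction | reference = calibration mean |
| Baseline | iterative lower-envelope polynomial | order 2 |
| SNV | per-row standardisation | sample SD (n − 1) |
| DT | polynomial detrend | order 2 |
| 1st/2nd Der | Savitzky–Golay derivative | window 13, polyorder 2 |

Conventions fixed once and tested: the SD convention is the sample one
throughout; derivatives are scaled by the wavelength step, so their
units are per nm (per nm² for the second derivative); smoothing is part
of the derivative operator, since differentiating raw spectra amplifies
noise. SNV here is the standard per-spectrum transform; descriptions of
SNV as acting "at each wavelength point" refer to the same operation
read along the other axis and are not what any chemometrics
implementation does.

Only MSC carries calibration statistics (its reference spectrum). The
reference is fitted on calibration rows, attached to the result, and
must be passed back in when transforming prediction rows
(`run_pipeline()` does this automatically), so prediction data can
never influence a fitted transform.

## Wavelength selection

Three selectors reduce the 320 bands to an informative subset. All
report the selected fraction as `round(100 * k / 320, 2)`.

**GA** (`ga_select()`): binary chromosomes, one gene per band;
population 50, at most 100 generations with early stop after 20
stagnant generations; roulette selection, single-point crossover at
probability 0.8, per-gene mutation at 0.01; all-zero chromosomes are
repaired by activating one random gene. The fitness function was open:
it is the negated k-fold RMSECV of a PLS1 model on the chromosome's
bands, with the component count chosen by the same cross-validation
(capped at 10, 5 folds), and one fold assignment drawn per run so
fitness values are comparable across generations. GA is stochastic by
nature: seeded runs reproduce exactly, different seeds may select
different bands.

**SPA** (`spa_select()`): for every start band a chain is grown by
repeatedly adding the band with the largest residual norm after
projecting out the chain's span (classical successive projections);
each (start, N) prefix with N = 1..20 is scored by the validation RMSE
of an ordinary least-squares fit. The validation split was unstated and
is fixed as the last quarter of the calibration rows — deterministic,
so SPA gives identical results on every call. Chains terminate early on
rank collapse, which the diagnostics record.

**CARS** (`cars_select()`): 50 Monte Carlo runs; each fits PLS1 on a
random 80 % row subset of the currently retained bands and weights
bands by |regression coefficient|. An exponentially decreasing function
with endpoints $r_1 = 1$ and $r_N = 2/p$ fixes the forced-elimination
schedule (fast phase, then fine phase), and adaptive reweighted
sampling — weighted draws with replacement — thins the survivors. The
draw count follows the EDF schedule on the **full** band count; drawing
only as many times as bands remain would compound the thinning and
collapse the trajectory within a few runs instead of tracking the
two-phase shape. Each run's retained set is scored by 10-fold RMSECV
and the minimiser wins. `max_bands` optionally restricts the winner to
sets a downstream model can consume; `run_pipeline()` sets it to
`n_cal - 2` whenever MLR is among the configured models, which is the
classical reason for selecting wavelengths at all: multiple linear
regression requires more samples than variables.

## Calibration models and evaluation

`fit_model()` covers MLR (ordinary least squares; exactly collinear
bands are aliased to zero coefficients, and the n ≤ p case is refused),
PLSR (NIPALS PLS1, shared with GA and CARS, components by 10-fold
RMSECV capped at min(15, n − 1)), PCR (components by the same rule,
with the PCA refitted inside every CV fold), and SVR (radial kernel via
e1071, with a small cost/gamma/epsilon grid scored by cross-validation
when no hyperparameters are given — none are prescribed by the
workflow itself).

Models are scored by
$$R^2 = 1 - \frac{\sum_i (y_i - \hat y_i)^2}{\sum_i (y_i - \bar y)^2},
\qquad
\mathrm{RMSE} = \sqrt{\tfrac1n \sum_i (y_i - \hat y_i)^2},$$
on the calibration set (Rc², RMSEC) and prediction set (Rp², RMSEP).
R² is returned unclipped — it is genuinely negative for predictors
worse than the mean, and flooring it would hide failures.

The calibration/prediction split (3:1) uses Kennard–Stone by default:
deterministic, and it places the extremes of predictor space in the
calibration set so prediction is interpolation. A seeded random split
is available. Since the original split rule for such experiments is
rarely reported, `run_pipeline()` records the split indices in its
result.

## Coefficient significance

`mlr_significance()` fits OLS on the selected bands and reports, per
band, the coefficient, its standard error (residual variance times the
inverse normal-equations diagonal), t value and two-sided p value on
n − k − 1 degrees of freedom. A band is flagged when |t| > 2 **or**
p < 0.05; the two sub-rules differ slightly at small n, so both are
reported beside the combined flag. No multiple-testing correction is
applied by default, matching common practice in this workflow; a
Benjamini–Hochberg option exists but is off. `band_overlap()`
summarises how two analytes' significant bands intersect and how much
of each set falls into a wavelength window such as the 470–700 nm
pigment region.

One caveat the tests make explicit: under multiplicative scatter,
bands far from an analyte's absorption features can be *genuinely*
predictive, because they let the model estimate each spectrum's scatter
slope. Significance then correctly flags them. Attributing significant
bands to absorption features alone is valid only when scatter is
negligible or corrected first.

## The synthetic data generator

No instrument data ships with the package; the generator
(`spectral_model_config()`, `generate_dataset()`) emulates the study
design so every stage is testable. Defaults encode the acquisition
protocol: 5 varieties x 12 fruit = 60 samples, 4 views each (240
spectra), 320 bands linearly spaced over 380–1018 nm.

Reference chemistry: each analyte is a truncated normal matched to the
population summaries (mean, SD, min, max) of starch 7.43 ± 2.69 %
[4.25, 10.88], VC 1.90 ± 0.43 per mille [1.02, 2.30], SSC
13.27 ± 1.60 % [11.40, 16.00], TA 3.41 ± 0.99 per mille [2.45, 5.14] —
only these four summaries are available, and a truncated normal is the
least-committal distribution matching them. Starch and vitamin C are
drawn jointly through a Gaussian copula with correlation 0.9 (they are
strongly associated in ripening fruit); other pairs are independent.

Spectra: a smooth baseline rising toward the NIR minus four Gaussian
absorption features near 500 nm (carotenoid), 680 nm (chlorophyll),
840 nm and 975 nm (O–H overtones of water/sugar), with widths
(35, 25, 28, 24) nm. Feature depths are linear in the analyte vector:
starch and vitamin C load only on the two pigment features (the
470–700 nm window), SSC and TA only on the two O–H features, and
within each pair the loading vectors are non-proportional so both
analytes stay identifiable from the two depths. On top of the clean
spectrum each view receives multiplicative scatter (slope SD 0.02,
offset SD 0.02), three broad random baseline undulations (amplitude SD
0.02, width 100 nm) standing in for illumination and surface-curvature
variation, and white noise (SD 5e-4, roughly what remains after
averaging an ROI of many thousand pixels). Reflectance is clipped to
[0, 1].

The noise magnitudes were calibrated, as part of constructing the
generator, so that the synthetic study occupies the performance regime
the workflow is designed for — full-spectrum PLSR around 0.95–0.99 and
the derivative-CARS-MLR pipeline above 0.9 for all four analytes — and
then frozen. Two findings from that calibration are worth recording.
First, low-rank additive nuisances (offsets, slopes, broad drift)
barely harm full-spectrum linear models: with 320 bands and a
four-dimensional signal, PLS simply learns coefficient vectors
orthogonal to the nuisance subspace. A visible advantage for
derivative preprocessing over raw spectra emerges only when the smooth
drift has high effective rank relative to the calibration size and the
absorption features are sharp — the regime the ranking tests construct
explicitly. Second, the multiplicative slope interacts with the mean
feature depths to create a nuisance direction nearly parallel to the
weakest analyte's signal in second-derivative space, which is why the
slope SD matters more than the white-noise floor.

`generate_cube()` additionally wraps one spectrum into a full raw
cube with dark/white frames (and optionally a specular blob inside the
fruit disk), constructed so that reflectance correction recovers the
input exactly in the noise-free mode — the fixture for the calibration
and ROI stages.

What the generator does **not** emulate: instrument line-shape and
stray light, variety-specific spectral signatures beyond loading
differences, spatial texture inside the fruit disk, wavelength
registration error, and any nonlinearity between chemistry and
absorbance. Passing tests therefore show the pipeline is correct and
well-behaved under the stated statistical structure, not that the
specific accuracy numbers transfer to real fruit.

## Problem sizes and numerical choices

The test suite and the acceptance script run everything at the study's
own scale — 60 samples x 4 views x 320 bands — plus a 65-band planted
fixture for selector recovery (20 GA seeds, 10 CARS seeds) and 5
seeded repetitions of the full pipeline; the complete suite finishes in
under a minute on one core. Numerical guards: NIPALS stops extracting
components when the residual covariance norm falls below 1e-12; SPA
terminates chains whose residual norms fall below 1e-10; MSC refuses
slopes below 1e-10 in magnitude; region growing treats a single-pixel
SD of zero as an exact-match criterion. Ties in `rank_preprocessing()`
break by lower RMSEP; `which.min`/`which.max` resolve remaining exact
ties by first index, making every ranking deterministic.

## Known limitations

* PLS1 only: one response at a time; multi-response joint regression is
  out of scope.
* The GA fitness and CARS scoring share the PLS1 core; a selector built
  around a different inner regressor would need its own fitness.
* Kennard–Stone is O(n²) in memory over samples — fine at laboratory
  scale, not meant for thousands of samples.
* SVR models do not serialise to JSON; keep the fitted object.
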