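# rotospec

Chemometrics for rotational hyperspectral imaging of fruit: predict
internal quality traits — starch (%), vitamin C (‰), soluble solids
(SSC, %) and titratable acid (TA, ‰) — from reflectance spectra
extracted from hyperspectral images of fruit rotated through four 90°
views. The package is aimed at spectroscopists and phenotyping groups
who need the whole workflow — calibration, region-of-interest
extraction, preprocessing, wavelength selection, regression,
coefficient significance — as tested, scriptable R functions rather
than point-and-click imaging software.

## What it implements

Starting from raw ENVI cubes (or the built-in synthetic generator):

1. **Reflectance calibration** — dark/white correction
   `R = (R_origin − R_dark) / (R_white − R_dark)`.
2. **ROI extraction** — seeded region growing (mean ± 2.2 SD admission,
   ≤ 50 rounds, 480 × 480 bounding-box cap) that rejects specular
   highlights; the ROI mean is the sample spectrum, and the four
   rotational views are averaged per fruit.
3. **Preprocessing** — nine transforms behind one registry: SG and
   moving-average smoothing, min–max normalisation, MSC, baseline
   correction, SNV, detrend, 1st and 2nd Savitzky–Golay derivatives.
4. **Wavelength selection** — genetic algorithm (pop 50, crossover 0.8,
   mutation 0.01, early stop after 20 stagnant generations), successive
   projections algorithm (N = 1–20, fully deterministic) and
   competitive adaptive reweighted sampling (50 Monte Carlo runs,
   exponentially decreasing retention from all bands to 2, 10-fold
   RMSECV winner).
5. **Regression** — SVR, PCR, PLSR (NIPALS), MLR, evaluated by
   `R² = 1 − Σ(yᵢ − ŷᵢ)²/Σ(yᵢ − ȳ)²` and
   `RMSE = √(Σ(yᵢ − ŷᵢ)²/n)` on a Kennard–Stone 3:1
   calibration/prediction split (Rc², RMSEC, Rp², RMSEP).
6. **Significance mapping** — per-band t and p values of the MLR
   coefficients (flagged when |t| > 2 or p < 0.05) and the band-overlap
   analysis between analytes.

A seeded synthetic generator emulates the full study design — 5
varieties × 12 fruit × 4 views, 320 bands over 380–1018 nm, absorption
features near 500/680/840/975 nm whose depths are linear in the
analytes — so the entire pipeline is testable without instrument data.
See `vignette("rotospec-methods")` for the models, parameter defaults
and design choices.

## Worked example

```r
library(rotospec)

cfg <- spectral_model_config(seed = 42)   # the default study design
ds  <- generate_dataset(cfg)
ds$spectra
#> spectra_matrix: 240 spectra x 320 bands (380-1018 nm)

res <- run_pipeline(ds$spectra, ds$reference,
                    pipeline_config(preprocess = "2nd Der",
                                    selectors  = c("FS", "CARS"),
                                    models     = c("PLSR", "MLR"),
                                    analytes   = c("starch", "ssc"),
                                    seed = 42))
res$table[, c("analyte", "model", "extraction", "n_wavelengths",
              "rc2", "rmsec", "rp2", "rmsep", "note")]
#>   analyte model extraction n_wavelengths   rc2  rmsec   rp2  rmsep note
#> 1  starch  PLSR         FS           320 0.998 0.0771 0.998 0.0875
#> 2  starch   MLR         FS           320    NA     NA    NA     NA    /
#> 3  starch  PLSR       CARS            38 1.000 0.0136 0.997 0.1054
#> 4  starch   MLR       CARS            38 1.000 0.0102 0.997 0.1081
#> 5     ssc  PLSR         FS           320 0.986 0.1269 0.989 0.1325
#> 6     ssc   MLR         FS           320    NA     NA    NA     NA    /
#> 7     ssc  PLSR       CARS            37 0.999 0.0249 0.977 0.1912
#> 8     ssc   MLR       CARS            37 1.000 0.0184 0.970 0.2180

res$selections[["2nd Der|starch|CARS"]]
#> CARS selection: 38 of 320 bands (11.88%)
```

Reading the table: each row is one (preprocess, selector, model)
combination for one analyte. `rc2`/`rmsec` score the 45-sample
calibration set, `rp2`/`rmsep` the 15-sample prediction set — starch
here is predicted with Rp² ≈ 0.997 (RMSEP ≈ 0.11 percentage points of
starch) from 38 selected bands (11.88 % of the spectrum). The `/` rows
mark MLR on the full spectrum, which is not applicable because 320
bands exceed the 45 calibration samples.

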