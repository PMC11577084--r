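test_that("reference chemistry has the right size, envelope and determinism", {
  cfg <- spectral_model_config(seed = 7)
  ref <- generate_reference_chemistry(cfg)
  expect_s3_class(ref, "reference_table")
  expect_equal(nrow(ref), 60)
  expect_equal(ref$sample_id[1], "A_1")
  expect_equal(ref$sample_id[60], "E_12")
  expect_equal(table(ref$variety), table(rep(LETTERS[1:5], each = 12)),
               ignore_attr = TRUE)

  # population envelope: no analyte leaves its min/max under defaults
  pop <- rotospec:::analyte_population()
  for (j in seq_len(nrow(pop))) {
    v <- ref[[pop$analyte[j]]]
    expect_true(all(is.finite(v) & v > 0))
    expect_true(all(v >= pop$min[j] & v <= pop$max[j]),
                label = paste(pop$analyte[j], "within population bounds"))
  }
  expect_true(all(ref$starch >= 4.25 & ref$starch <= 10.88))
  expect_true(all(ref$ssc >= 11.40 & ref$ssc <= 16.00))

  expect_identical(ref, generate_reference_chemistry(cfg))
  cfg2 <- spectral_model_config(seed = 8)
  expect_false(identical(ref$starch,
                         generate_reference_chemistry(cfg2)$starch))
})

test_that("starch and vitamin C carry the configured correlation", {
  cfg <- spectral_model_config(fruit_per_variety = 120,
                               starch_vc_correlation = 0.95, seed = 3)
  ref <- generate_reference_chemistry(cfg)
  expect_equal(nrow(ref), 600)
  expect_lt(abs(cor(ref$starch, ref$vc) - 0.95), 0.05)

  cfg0 <- spectral_model_config(fruit_per_variety = 120,
                                starch_vc_correlation = 0, seed = 3)
  ref0 <- generate_reference_chemistry(cfg0)
  expect_lt(abs(cor(ref0$starch, ref0$vc)), 0.15)
})

test_that("configuration errors are caught", {
  expect_error(spectral_model_config(n_varieties = 0), "counts")
  expect_error(spectral_model_config(starch_vc_correlation = 1.2),
               "correlation")
  expect_error(spectral_model_config(loading_matrix = diag(3)),
               "loading_matrix")
  expect_error(spectral_model_config(peak_widths = c(10, 10)),
               "peak_widths")
})

test_that("spectra generation is affine in the analytes when noise-free", {
  cfg <- noise_free_config(views_per_sample = 1, seed = 5)
  ref <- generate_reference_chemistry(cfg)
  sp <- generate_spectra(ref, cfg)
  expect_equal(nrow(sp$values), 60)
  expect_equal(ncol(sp$values), 320)
  expect_equal(range(sp$wavelengths), c(380, 1018))

  # band-wise regression on the analytes leaves machine-precision residuals
  A <- cbind(1, as.matrix(ref[, c("starch", "vc", "ssc", "ta")]))
  H <- A %*% solve(crossprod(A), t(A))
  resid <- sp$values - H %*% sp$values
  expect_lt(max(abs(resid)), 1e-9)
})

test_that("default acquisition bookkeeping matches the rotational protocol", {
  cfg <- spectral_model_config(seed = 2)
  ds <- generate_dataset(cfg)
  expect_equal(nrow(ds$spectra$values), 240)     # 60 samples x 4 views
  expect_equal(nrow(ds$spectra_mean$values), 60)
  expect_equal(ncol(ds$spectra$values), 320)
  expect_identical(ds$spectra,
                   generate_spectra(ds$reference, cfg))  # determinism
  expect_true(all(ds$spectra$values >= 0 & ds$spectra$values <= 1))
})

test_that("doubling the noise raises band-wise residual variance", {
  cfg1 <- spectral_model_config(noise_sd = 0.002, wiggle_sd = 0,
                                scatter_slope_sd = 0,
                                scatter_offset_sd = 0, seed = 9)
  cfg2 <- spectral_model_config(noise_sd = 0.004, wiggle_sd = 0,
                                scatter_slope_sd = 0,
                                scatter_offset_sd = 0, seed = 9)
  ref <- generate_reference_chemistry(cfg1)
  # residual variance of the views around their per-sample mean
  v <- function(cfg) {
    sp <- generate_spectra(ref, cfg)
    agg <- aggregate_views(sp)
    mean(apply(sp$values - agg$values[rep(1:60, each = 4), ], 2, var))
  }
  expect_gt(v(cfg2), v(cfg1))
})

test_that("synthetic cubes invert exactly under reflectance correction", {
  spec <- 0.2 + 0.4 * sin(seq(0, 3, length.out = 12))^2
  cub <- generate_cube(spec, 16, 16, seed = 1, noise_sd = 0)
  cal <- reflectance_correct(cub$origin, cub$frames)
  expect_equal(cal$values[8, 8, ], spec, tolerance = 1e-12)
  expect_equal(cal$values[1, 1, ], rep(cub$background, 12),
               tolerance = 1e-12)

  cubn <- generate_cube(spec, 16, 16, seed = 1, noise_sd = 5)
  caln <- reflectance_correct(cubn$origin, cubn$frames)
  expect_lt(max(abs(caln$values[8, 8, ] - spec)), 0.05)

  expect_error(generate_cube(c(0.5, 1.4), 16, 16), "\\[0, 1\\]")
  expect_error(generate_cube(spec, 4, 16), ">= 8")
})

test_that("reference and spectra CSV round-trips preserve content", {
  cfg <- spectral_model_config(n_varieties = 2, fruit_per_variety = 3,
                               n_bands = 12, seed = 4)
  ds <- generate_dataset(cfg)
  f1 <- tempfile(fileext = ".csv")
  write_reference_csv(ds$reference, f1)
  back <- read.csv(f1)
  expect_equal(back$starch, ds$reference$starch, tolerance = 1e-8)
  f2 <- tempfile(fileext = ".csv")
  write_spectra_csv(ds$spectra, f2)
  sp <- read_spectra_csv(f2)
  expect_equal(sp$values, ds$spectra$values, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(sp$wavelengths, ds$spectra$wavelengths, tolerance = 1e-8)
})
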