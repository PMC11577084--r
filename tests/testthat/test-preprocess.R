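wl20 <- seq(380, 1018, length.out = 20)

rand_spectra <- function(n = 5, p = 20, seed = 1) {
  rotospec:::with_seed(seed,
    spectra_matrix(matrix(runif(n * p, 0.2, 0.8), n, p),
                   seq(380, 1018, length.out = p)))
}

test_that("every transform preserves row and band counts and provenance", {
  X <- rand_spectra(4, 41)
  for (m in preprocess_methods()) {
    out <- apply_pipeline(X, m)
    expect_equal(dim(out$values), dim(X$values), label = m)
    expect_equal(length(out$provenance), 1L, label = m)
    out2 <- apply_pipeline(out, "SNV")
    expect_equal(length(out2$provenance), 2L)
  }
  expect_error(apply_pipeline(X, "wavelet"), "unknown")
})

test_that("Savitzky-Golay smoothing reproduces low-degree polynomials", {
  wl <- seq(380, 1018, length.out = 50)
  u <- (wl - 700) / 100
  X <- rbind(2 + 3 * u + 0.5 * u^2,   # degree 2 with polyorder 2
             rep(1.5, 50))            # constant
  out <- sg_smooth(spectra_matrix(X, wl), window = 11, polyorder = 2)
  expect_equal(out$values, X, tolerance = 1e-9, ignore_attr = TRUE)

  # noisy sine: smoothing strictly reduces the noise level
  set.seed(1)
  clean <- sin(seq(0, 2 * pi, length.out = 50))
  noisy <- clean + rnorm(50, sd = 0.05)
  sm <- sg_smooth(spectra_matrix(rbind(noisy), wl))$values[1, ]
  expect_lt(sd(sm - clean), sd(noisy - clean))

  expect_error(sg_smooth(rand_spectra(), window = 4), "odd")
  expect_error(sg_smooth(rand_spectra(2, 9), window = 11), "band count")
})

test_that("moving average matches hand values and passes lines through", {
  X <- spectra_matrix(rbind(c(0, 3, 0, 0, 0)), 1:5)
  out <- ma_smooth(X, window = 3)
  expect_equal(out$values[1, 2], 1)          # three-point mean
  expect_equal(ma_smooth(spectra_matrix(rbind(rep(2, 9)), 1:9),
                         3)$values[1, ], rep(2, 9))
  # linear ramp unchanged in the interior (centred mean of a line)
  ramp <- seq(1, 9, length.out = 9)
  out2 <- ma_smooth(spectra_matrix(rbind(ramp), 1:9), window = 3)
  expect_equal(out2$values[1, 2:8], ramp[2:8], tolerance = 1e-12)
})

test_that("min-max normalisation maps to [0,1] and is idempotent", {
  X <- spectra_matrix(rbind(c(2, 4, 6)), 1:3)
  out <- minmax_normalize(X)
  expect_equal(out$values[1, ], c(0, 0.5, 1))
  expect_equal(minmax_normalize(out)$values, out$values)  # idempotent
  expect_error(minmax_normalize(spectra_matrix(rbind(c(1, 1, 1)), 1:3)),
               "row 1")
})

test_that("MSC inverts per-row affine scatter against the reference", {
  X <- rand_spectra(3, 30, seed = 5)
  ref <- colMeans(X$values)
  # a row equal to the reference is unchanged; an affine distortion of
  # the reference maps back to the reference exactly
  rows <- rbind(ref, 2 * ref + 5, 0.5 * ref - 1)
  out <- msc(spectra_matrix(rows, X$wavelengths), reference = ref)
  for (i in 1:3)
    expect_equal(out$values[i, ], ref, tolerance = 1e-10,
                 ignore_attr = TRUE)

  # planted multiplicative scatter: post-MSC between-view variance drops
  cfg <- spectral_model_config(noise_sd = 0, wiggle_sd = 0,
                               scatter_slope_sd = 0.08,
                               scatter_offset_sd = 0.04, seed = 11)
  ds <- generate_dataset(cfg, aggregate = FALSE)
  corrected <- msc(ds$spectra)
  within_view_var <- function(M, id) {
    mean(sapply(unique(id), function(s)
      mean(apply(M[id == s, , drop = FALSE], 2, var))))
  }
  expect_lt(within_view_var(corrected$values, ds$spectra$sample_id),
            within_view_var(ds$spectra$values, ds$spectra$sample_id))

  expect_error(msc(spectra_matrix(rbind(rep(1, 5)), 1:5),
                   reference = rep(1, 5)), "degenerate")
})

test_that("MSC calibration reference is frozen for prediction rows", {
  X <- rand_spectra(6, 25, seed = 2)
  cal <- msc(X)
  ref <- attr(cal, "msc_reference")
  newrow <- spectra_matrix(rbind(0.3 + 0.9 * ref), X$wavelengths)
  p1 <- msc(newrow, reference = ref)
  # changing the "prediction set" composition must not change the result
  tworows <- spectra_matrix(rbind(0.3 + 0.9 * ref, runif(25)),
                            X$wavelengths)
  p2 <- msc(tworows, reference = ref)
  expect_equal(p1$values[1, ], p2$values[1, ], tolerance = 1e-12)
})

test_that("baseline correction and detrending null their polynomial", {
  wl <- seq(380, 1018, length.out = 40)
  u <- (wl - mean(wl)) / 100
  quad <- 3 + 0.5 * u + 0.2 * u^2
  for (f in list(baseline_correct, detrend)) {
    out <- f(spectra_matrix(rbind(quad), wl))
    expect_lt(max(abs(out$values)), 1e-8)
  }
  # constant offset row maps to zero mean
  out0 <- baseline_correct(spectra_matrix(rbind(rep(2, 40)), wl))
  expect_lt(max(abs(out0$values)), 1e-8)
  expect_equal(mean(detrend(spectra_matrix(rbind(runif(40)),
                                           wl))$values), 0,
               tolerance = 1e-10)

  # a peak on a quadratic survives away from the edges
  peak <- 0.5 * exp(-0.5 * ((wl - 700) / 30)^2)
  out2 <- baseline_correct(spectra_matrix(rbind(quad + peak), wl))
  mid <- which(wl > 550 & wl < 850)
  expect_lt(max(abs(out2$values[1, mid] - peak[mid])), 0.06)
})

test_that("SNV standardises rows under the sample-SD convention", {
  out <- snv(spectra_matrix(rbind(c(1, 2, 3)), 1:3))
  expect_equal(out$values[1, ], c(-1, 0, 1))   # sample SD = 1
  X <- rand_spectra(3, 15, seed = 7)
  out2 <- snv(X)
  expect_equal(rowMeans(out2$values), rep(0, 3), tolerance = 1e-12)
  expect_equal(apply(out2$values, 1, sd), rep(1, 3), tolerance = 1e-12)
  # affine invariance
  out3 <- snv(spectra_matrix(5 + 2 * X$values, X$wavelengths))
  expect_equal(out3$values, out2$values, tolerance = 1e-12)
  expect_error(snv(spectra_matrix(rbind(rep(1, 4)), 1:4)), "zero SD")
})

test_that("derivatives are exact on polynomials and locate planted peaks", {
  wl <- seq(380, 1018, length.out = 80)
  step <- diff(wl)[1]
  s <- 0.003
  lin <- 1 + s * (wl - 380)
  d1 <- derivative(spectra_matrix(rbind(lin), wl), order = 1)
  expect_equal(d1$values[1, ], rep(s, 80), tolerance = 1e-10)
  d2 <- derivative(spectra_matrix(rbind(lin), wl), order = 2)
  expect_lt(max(abs(d2$values)), 1e-10)

  a <- 2e-5
  quad <- a * (wl - 700)^2
  d2q <- derivative(spectra_matrix(rbind(quad), wl), order = 2)
  expect_equal(d2q$values[1, ], rep(2 * a, 80), tolerance = 1e-10)

  # first-derivative zero crossing at a planted Gaussian centre
  center <- wl[45]
  g <- exp(-0.5 * ((wl - center) / 40)^2)
  d1g <- derivative(spectra_matrix(rbind(g), wl), order = 1)$values[1, ]
  crossings <- which(diff(sign(d1g)) != 0)
  expect_lte(min(abs(wl[crossings] - center)), step)

  expect_error(derivative(rand_spectra(), order = 3), "order")
})
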