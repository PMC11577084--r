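# Shared fixtures, all generated in code at test time.

# Planted-signal fixture: a handful of informative bands buried in noise
# bands, used to probe whether selectors recover known truth. The
# informative columns carry twice the variance of the noise columns, as
# absorption features do relative to flat background bands.
planted_bands_fixture <- function(n = 80, p = 65,
                                  informative = c(5, 17, 29, 43, 58),
                                  coefs = c(3, -2.5, 2, 3.5, -3),
                                  noise_sd = 0.2, seed = 42) {
  stopifnot(length(informative) == length(coefs))
  rotospec:::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    X[, informative] <- 2 * X[, informative]
    y <- drop(X[, informative] %*% coefs) + rnorm(n, sd = noise_sd)
    list(X = X, y = y, informative = informative)
  })
}

# Small noise-free configuration for exactness tests.
noise_free_config <- function(...) {
  spectral_model_config(noise_sd = 0, wiggle_sd = 0, scatter_slope_sd = 0,
                        scatter_offset_sd = 0, ...)
}

# Sharp-feature configuration: narrow absorption peaks plus strong
# smooth per-view drift, the regime where derivative preprocessing has a
# visible edge over raw spectra.
sharp_feature_config <- function(seed = 1L) {
  spectral_model_config(seed = seed, peak_widths = c(12, 9, 10, 8),
                        wiggle_sd = 0.05, wiggle_width = 40)
}

expect_same_spectra <- function(a, b, tol = 1e-12) {
  expect_equal(a$values, b$values, tolerance = tol)
  expect_equal(a$wavelengths, b$wavelengths, tolerance = tol)
}
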