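# Nine spectral preprocessing transforms behind one registry with a
# uniform contract: every transform takes a spectra_matrix (or bare
# matrix), preserves row and band counts, and appends one provenance
# record. The per-row transforms carry no calibration statistics; MSC is
# the exception and freezes its reference spectrum for reuse on
# prediction rows.

record <- function(X, method, params = list()) {
  X$provenance <- c(X$provenance, list(list(method = method,
                                            params = params)))
  X
}

sg_check <- function(window, polyorder, n_bands) {
  if (window %% 2 == 0) stop_config("window must be odd")
  if (window <= polyorder) stop_config("window must exceed polyorder")
  if (window >= n_bands) stop_config("window must be smaller than the ",
                                     "band count")
}

#' Savitzky-Golay smoothing
#'
#' Per-row local least-squares polynomial smoothing. Rows that are
#' polynomials of degree at most `polyorder` are reproduced to machine
#' precision; edges are handled by the filter's polynomial edge fits so
#' the band count is preserved.
#'
#' @param X a [spectra_matrix()] or numeric matrix (spectra in rows).
#' @param window odd window length in bands.
#' @param polyorder polynomial degree, less than `window`.
#' @return a [spectra_matrix()] of the same shape.
#' @export
sg_smooth <- function(X, window = 11, polyorder = 2) {
  X <- as_spectra_matrix(X)
  sg_check(window, polyorder, ncol(X$values))
  X$values <- t(apply(X$values, 1, signal::sgolayfilt, p = polyorder,
                      n = window))
  record(X, "SG", list(window = window, polyorder = polyorder))
}

#' Moving-average smoothing
#'
#' Per-row centred moving mean with reflect-padded edges.
#'
#' @inheritParams sg_smooth
#' @param window odd window length in bands.
#' @return a [spectra_matrix()] of the same shape.
#' @export
ma_smooth <- function(X, window = 5) {
  X <- as_spectra_matrix(X)
  p <- ncol(X$values)
  if (window %% 2 == 0) stop_config("window must be odd")
  if (window >= p) stop_config("window must be smaller than the band count")
  h <- (window - 1) / 2
  pad <- c((h + 1):2, seq_len(p), (p - 1):(p - h))   # reflect without repeat
  X$values <- t(apply(X$values, 1, function(x) {
    as.numeric(stats::filter(x[pad], rep(1 / window, window),
                             sides = 2))[(h + 1):(h + p)]
  }))
  record(X, "MA", list(window = window))
}

#' Min-max normalisation
#'
#' Scales each spectrum to `[0, 1]`: `(x - min) / (max - min)` per row.
#' Idempotent, and invariant to positive affine changes of a row.
#'
#' @inheritParams sg_smooth
#' @return a [spectra_matrix()] of the same shape.
#' @export
minmax_normalize <- function(X) {
  X <- as_spectra_matrix(X)
  rmin <- apply(X$values, 1, min)
  rmax <- apply(X$values, 1, max)
  flat <- which(rmax == rmin)
  if (length(flat))
    stop_config("constant spectrum cannot be min-max normalised (row ",
                flat[1], ")")
  X$values <- (X$values - rmin) / (rmax - rmin)
  record(X, "NM", list())
}

#' Multiplicative scatter correction
#'
#' Regresses each spectrum on a reference spectrum, `x ~ a + b * ref`,
#' and returns `(x - a) / b`, removing per-spectrum additive offsets and
#' multiplicative scaling from light scattering. The default reference is
#' the column mean of the calibration matrix; it is stored in the result
#' (`msc_reference` attribute and provenance) and must be passed back in
#' when transforming prediction rows, so calibration statistics never
#' leak.
#'
#' @inheritParams sg_smooth
#' @param reference `"mean"` or a numeric vector of band length.
#' @param tol slopes with `|b| < tol` raise a degenerate-fit error.
#' @return a [spectra_matrix()]; the reference used is attached as
#'   attribute `msc_reference`.
#' @export
msc <- function(X, reference = "mean", tol = 1e-10) {
  X <- as_spectra_matrix(X)
  ref <- if (is.character(reference)) colMeans(X$values)
         else as.numeric(reference)
  if (length(ref) != ncol(X$values))
    stop_config("reference length must match band count")
  refc <- ref - mean(ref)
  ss <- sum(refc^2)
  if (ss < tol) stop_config("degenerate MSC reference (constant)")
  b <- drop(X$values %*% refc) / ss
  a <- rowMeans(X$values) - b * mean(ref)
  if (any(abs(b) < tol))
    stop_config("degenerate MSC fit (|slope| < tol) in row ",
                which(abs(b) < tol)[1])
  X$values <- (X$values - a) / b
  X <- record(X, "MSC", list(reference = ref))
  attr(X, "msc_reference") <- ref
  X
}

# Polynomial design matrix in centred/scaled wavelength, for stable fits.
poly_basis <- function(wl, order) {
  u <- (wl - mean(wl)) / (diff(range(wl)) / 2)
  outer(u, 0:order, `^`)
}

#' Baseline correction
#'
#' Subtracts a low-order polynomial baseline fitted per row by iterative
#' lower-envelope reweighting (the fit is repeated on `pmin(x, fit)`, so
#' positive peaks are peeled off and the polynomial follows the
#' underlying drift). A row that is exactly a polynomial of the given
#' order maps to zero.
#'
#' @inheritParams sg_smooth
#' @param order polynomial order of the baseline.
#' @param max_iter maximum envelope refinement iterations.
#' @return a [spectra_matrix()] of the same shape.
#' @export
baseline_correct <- function(X, order = 2, max_iter = 10) {
  X <- as_spectra_matrix(X)
  B <- poly_basis(X$wavelengths, order)
  qrB <- qr(B)
  X$values <- t(apply(X$values, 1, function(x) {
    z <- x
    for (i in seq_len(max_iter)) {
      fit <- drop(B %*% qr.coef(qrB, z))
      znew <- pmin(z, fit)
      if (max(abs(znew - z)) < 1e-12) { z <- znew; break }
      z <- znew
    }
    x - drop(B %*% qr.coef(qrB, z))
  }))
  record(X, "Baseline", list(order = order))
}

#' Standard normal variate transform
#'
#' Centres and scales each spectrum to mean 0, SD 1 (sample SD, `n - 1`
#' denominator). Invariant to per-row affine changes of the input.
#'
#' @inheritParams sg_smooth
#' @return a [spectra_matrix()] of the same shape.
#' @export
snv <- function(X) {
  X <- as_spectra_matrix(X)
  mu <- rowMeans(X$values)
  s <- apply(X$values, 1, stats::sd)
  zero <- which(s == 0)
  if (length(zero))
    stop_config("constant spectrum has zero SD (row ", zero[1], ")")
  X$values <- (X$values - mu) / s
  record(X, "SNV", list())
}

#' Detrend transform
#'
#' Per-row residual of an ordinary least-squares polynomial fit in
#' wavelength (order 2 by default, the classical detrend convention).
#' Output rows have zero mean for any `order >= 0`.
#'
#' @inheritParams baseline_correct
#' @return a [spectra_matrix()] of the same shape.
#' @export
detrend <- function(X, order = 2) {
  X <- as_spectra_matrix(X)
  B <- poly_basis(X$wavelengths, order)
  H <- B %*% solve(crossprod(B), t(B))
  X$values <- X$values - X$values %*% t(H)
  record(X, "DT", list(order = order))
}

#' Savitzky-Golay derivative
#'
#' Smoothed first or second derivative with respect to wavelength
#' (per-nm units: the filter is scaled by the wavelength step).
#' Smoothing is part of the operator, so spectral noise is suppressed
#' before differentiation; the band count is preserved so indices stay
#' aligned with the wavelength grid for feature selection.
#'
#' @inheritParams sg_smooth
#' @param order derivative order, 1 or 2.
#' @param window odd smoothing window in bands.
#' @param polyorder fitting polynomial degree (at least `order`).
#' @return a [spectra_matrix()] of the same shape, units per nm (or per
#'   nm squared).
#' @export
derivative <- function(X, order = 1, window = 13, polyorder = 2) {
  if (!order %in% c(1, 2)) stop_config("derivative order must be 1 or 2")
  X <- as_spectra_matrix(X)
  sg_check(window, polyorder, ncol(X$values))
  if (polyorder < order) stop_config("polyorder must be >= order")
  step <- mean(diff(X$wavelengths))
  X$values <- t(apply(X$values, 1, signal::sgolayfilt, p = polyorder,
                      n = window, m = order, ts = step))
  record(X, if (order == 1) "1st Der" else "2nd Der",
         list(window = window, polyorder = polyorder))
}

# Registry over the nine named methods plus the identity.
.preprocess_registry <- list(
  "Origin" = function(X, params) record(as_spectra_matrix(X), "Origin"),
  "SG" = function(X, params) do.call(sg_smooth, c(list(X), params)),
  "MA" = function(X, params) do.call(ma_smooth, c(list(X), params)),
  "NM" = function(X, params) minmax_normalize(X),
  "MSC" = function(X, params) do.call(msc, c(list(X), params)),
  "Baseline" = function(X, params) do.call(baseline_correct,
                                           c(list(X), params)),
  "SNV" = function(X, params) snv(X),
  "DT" = function(X, params) do.call(detrend, c(list(X), params)),
  "1st Der" = function(X, params)
    do.call(derivative, c(list(X, order = 1), params)),
  "2nd Der" = function(X, params)
    do.call(derivative, c(list(X, order = 2), params)))

#' Names of the available preprocessing methods
#'
#' @return character vector of registry names.
#' @export
preprocess_methods <- function() names(.preprocess_registry)

#' Apply a named preprocessing method
#'
#' Dispatches on the registry of the nine preprocessing transforms (plus
#' the identity, `"Origin"`), recording the call in the result's
#' provenance.
#'
#' @inheritParams sg_smooth
#' @param method_name one of [preprocess_methods()].
#' @param params named list of parameters forwarded to the transform.
#' @return a [spectra_matrix()].
#' @export
#' @examples
#' sp <- spectra_matrix(matrix(runif(40), 4, 10), seq(380, 1018,
#'                      length.out = 10))
#' apply_pipeline(sp, "SNV")
apply_pipeline <- function(X, method_name, params = list()) {
  f <- .preprocess_registry[[method_name]]
  if (is.null(f))
    stop_config("unknown preprocessing method '", method_name,
                "'; available: ", paste(preprocess_methods(),
                                        collapse = ", "))
  f(X, params)
}
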