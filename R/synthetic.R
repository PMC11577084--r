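#' Configuration of the synthetic acquisition model
#'
#' Bundles every knob of the synthetic data generator. The defaults encode
#' the study design the package is built around: 5 varieties x 12 fruit =
#' 60 samples, each imaged at 4 rotational views (240 spectra), on a
#' 320-band wavelength grid spanning 380-1018 nm, with absorption features
#' near 500 and 680 nm (carotenoid / chlorophyll) whose depths are driven
#' by starch and vitamin C, and near 840 and 975 nm (sugar / water O-H
#' overtones) driven by soluble solids and titratable acid.
#'
#' @param n_varieties number of varieties (labelled A, B, C, ...).
#' @param fruit_per_variety fruit sampled per variety.
#' @param views_per_sample rotational views acquired per fruit.
#' @param n_bands number of spectral bands.
#' @param wavelength_min,wavelength_max wavelength grid limits in nm.
#' @param peak_centers,peak_widths Gaussian absorption feature centres and
#'   widths (standard deviations), nm.
#' @param loading_matrix `length(peak_centers)` x 4 matrix mapping the
#'   analyte vector (starch, vc, ssc, ta) to peak depths in reflectance
#'   units. Rows follow `peak_centers`.
#' @param scatter_slope_sd,scatter_offset_sd standard deviations of the
#'   per-view multiplicative scatter slope (around 1) and additive offset
#'   (around 0).
#' @param noise_sd standard deviation of additive white noise, reflectance
#'   units, applied per band after scatter.
#' @param wiggle_sd amplitude SD (reflectance units) of smooth per-view
#'   baseline undulations — broad random Gaussian bumps emulating
#'   illumination and surface-curvature variation; they corrupt raw
#'   spectra but are largely removed by derivative preprocessing.
#' @param wiggle_width width (SD, nm) of the baseline undulations; much
#'   broader than the absorption features.
#' @param starch_vc_correlation Gaussian-copula correlation between starch
#'   and vitamin C; other analyte pairs are independent.
#' @param seed integer seed making all draws reproducible.
#' @return an object of class `spectral_model_config` (a validated list).
#' @export
spectral_model_config <- function(n_varieties = 5,
                                  fruit_per_variety = 12,
                                  views_per_sample = 4,
                                  n_bands = 320,
                                  wavelength_min = 380,
                                  wavelength_max = 1018,
                                  peak_centers = c(500, 680, 840, 975),
                                  peak_widths = c(35, 25, 28, 24),
                                  loading_matrix = NULL,
                                  scatter_slope_sd = 0.02,
                                  scatter_offset_sd = 0.02,
                                  noise_sd = 5e-4,
                                  wiggle_sd = 0.02,
                                  wiggle_width = 100,
                                  starch_vc_correlation = 0.9,
                                  seed = 1L) {
  counts <- c(n_varieties = n_varieties, fruit_per_variety = fruit_per_variety,
              views_per_sample = views_per_sample, n_bands = n_bands)
  if (any(counts < 1))
    stop_config("counts must be positive: ",
                paste(names(counts)[counts < 1], collapse = ", "))
  if (abs(starch_vc_correlation) > 1)
    stop_config("|starch_vc_correlation| must not exceed 1")
  if (wavelength_max <= wavelength_min)
    stop_config("wavelength_max must exceed wavelength_min")
  if (length(peak_widths) != length(peak_centers))
    stop_config("peak_widths and peak_centers must have equal length")
  if (is.null(loading_matrix)) loading_matrix <- default_loading_matrix()
  loading_matrix <- as.matrix(loading_matrix)
  if (nrow(loading_matrix) != length(peak_centers) ||
      ncol(loading_matrix) != 4L)
    stop_config("loading_matrix must be length(peak_centers) x 4 ",
                "(analytes: starch, vc, ssc, ta)")
  structure(list(n_varieties = as.integer(n_varieties),
                 fruit_per_variety = as.integer(fruit_per_variety),
                 views_per_sample = as.integer(views_per_sample),
                 n_bands = as.integer(n_bands),
                 wavelength_min = wavelength_min,
                 wavelength_max = wavelength_max,
                 peak_centers = peak_centers,
                 peak_widths = peak_widths,
                 loading_matrix = loading_matrix,
                 scatter_slope_sd = scatter_slope_sd,
                 scatter_offset_sd = scatter_offset_sd,
                 noise_sd = noise_sd,
                 wiggle_sd = wiggle_sd,
                 wiggle_width = wiggle_width,
                 starch_vc_correlation = starch_vc_correlation,
                 seed = as.integer(seed)),
            class = "spectral_model_config")
}

# Peak-depth loadings per unit analyte. Starch and vitamin C drive only the
# 500/680 nm pigment features (both inside the 470-700 nm window), soluble
# solids and titratable acid only the 840/975 nm O-H features. Within each
# pair the two loading vectors are deliberately non-proportional so the two
# analytes stay identifiable from the two depths.
default_loading_matrix <- function() {
  m <- rbind(c(0.006, 0.060, 0, 0),    # 500 nm
             c(0.016, 0.015, 0, 0),    # 680 nm
             c(0, 0, 0.016, 0.004),    # 840 nm
             c(0, 0, 0.010, 0.020))    # 975 nm
  dimnames(m) <- list(c("500", "680", "840", "975"),
                      c("starch", "vc", "ssc", "ta"))
  m
}

#' Wavelength grid of a configuration
#'
#' Linear grid with `n_bands` points over `[wavelength_min,
#' wavelength_max]` nm.
#'
#' @param config a [spectral_model_config()].
#' @return numeric vector of band-centre wavelengths, nm.
#' @export
wavelength_grid <- function(config) {
  seq(config$wavelength_min, config$wavelength_max,
      length.out = config$n_bands)
}

# Per-analyte population summaries the reference generator reproduces:
# mean, SD and hard min/max (truncation bounds) of starch (%), vitamin C
# (per mille), soluble solids (%), titratable acid (per mille).
analyte_population <- function() {
  data.frame(analyte = c("starch", "vc", "ssc", "ta"),
             mean = c(7.43, 1.90, 13.27, 3.41),
             sd = c(2.69, 0.43, 1.60, 0.99),
             min = c(4.25, 1.02, 11.40, 2.45),
             max = c(10.88, 2.30, 16.00, 5.14))
}

# Truncated-normal quantile function via the probability transform.
qtruncnorm <- function(u, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + u * (phi - plo), mean, sd)
}

#' Generate a synthetic reference chemistry table
#'
#' Draws one row per fruit sample with the four wet-chemistry reference
#' values. Each analyte follows a truncated normal matched to the target
#' population's mean, SD and min/max; starch and vitamin C are drawn
#' jointly through a Gaussian copula with correlation
#' `config$starch_vc_correlation`, the other pairs independently.
#'
#' @param config a [spectral_model_config()].
#' @return a `data.frame` of class `reference_table` with columns
#'   `sample_id` (e.g. `"A_1"`), `variety`, `starch` (percent), `vc`
#'   (per mille), `ssc` (percent), `ta` (per mille).
#' @export
#' @examples
#' ref <- generate_reference_chemistry(spectral_model_config(seed = 7))
#' summary(ref$starch)
generate_reference_chemistry <- function(config) {
  stopifnot(inherits(config, "spectral_model_config"))
  pop <- analyte_population()
  n <- config$n_varieties * config$fruit_per_variety
  rho <- config$starch_vc_correlation
  with_seed(config$seed, {
    z1 <- rnorm(n)
    z2 <- rho * z1 + sqrt(max(0, 1 - rho^2)) * rnorm(n)
    u <- cbind(starch = stats::pnorm(z1), vc = stats::pnorm(z2),
               ssc = runif(n), ta = runif(n))
    vals <- vapply(seq_len(4), function(j) {
      p <- pop[j, ]
      qtruncnorm(u[, pop$analyte[j]], p$mean, p$sd, p$min, p$max)
    }, numeric(n))
    colnames(vals) <- pop$analyte
    variety <- rep(LETTERS[seq_len(config$n_varieties)],
                   each = config$fruit_per_variety)
    idx <- rep(seq_len(config$fruit_per_variety), config$n_varieties)
    out <- data.frame(sample_id = paste(variety, idx, sep = "_"),
                      variety = variety, vals,
                      stringsAsFactors = FALSE)
    class(out) <- c("reference_table", "data.frame")
    out
  })
}

#' Construct a spectra matrix container
#'
#' The working currency of the modelling stages: an `n_spectra x n_bands`
#' matrix of mean-ROI reflectance (or transformed units) with its
#' wavelength grid, row identity, and an append-only provenance trail of
#' applied transforms.
#'
#' @param values numeric matrix, spectra in rows.
#' @param wavelengths numeric vector, nm, one per column.
#' @param sample_id character vector of sample labels, one per row.
#' @param view integer view index per row (1 for aggregated spectra).
#' @param provenance list of transform records.
#' @return an object of class `spectra_matrix`.
#' @export
spectra_matrix <- function(values, wavelengths, sample_id = NULL,
                           view = NULL, provenance = list()) {
  values <- as.matrix(values)
  if (ncol(values) != length(wavelengths))
    stop_config("wavelength vector length must match column count")
  if (is.null(sample_id)) sample_id <- as.character(seq_len(nrow(values)))
  if (is.null(view)) view <- rep(1L, nrow(values))
  structure(list(values = values, wavelengths = as.numeric(wavelengths),
                 sample_id = as.character(sample_id),
                 view = as.integer(view), provenance = provenance),
            class = "spectra_matrix")
}

#' @export
print.spectra_matrix <- function(x, ...) {
  cat(sprintf("spectra_matrix: %d spectra x %d bands (%.0f-%.0f nm)\n",
              nrow(x$values), ncol(x$values), min(x$wavelengths),
              max(x$wavelengths)))
  if (length(x$provenance))
    cat("transforms:", paste(vapply(x$provenance, `[[`, "", "method"),
                             collapse = " -> "), "\n")
  invisible(x)
}

#' @export
dim.spectra_matrix <- function(x) dim(x$values)

# Coerce a plain matrix into a spectra_matrix; pass through otherwise.
as_spectra_matrix <- function(X, wavelengths = NULL) {
  if (inherits(X, "spectra_matrix")) return(X)
  X <- as.matrix(X)
  if (is.null(wavelengths)) wavelengths <- seq_len(ncol(X))
  spectra_matrix(X, wavelengths)
}

# Smooth reflectance baseline rising toward the NIR, on u = (lambda -
# min) / range in [0, 1]. Kept away from 0/1 so clipping rarely binds.
reflectance_baseline <- function(u) 0.25 + 0.50 * u - 0.15 * u^2

#' Generate per-view reflectance spectra from reference chemistry
#'
#' Builds one spectrum per (sample, view) as a smooth baseline minus a sum
#' of Gaussian absorption features whose depths are linear in the sample's
#' analyte vector through `config$loading_matrix`, then applies per-view
#' multiplicative scatter (random slope and offset), smooth per-view
#' baseline undulations, and additive white noise, and clips to `[0, 1]`.
#'
#' @param ref a `reference_table` from [generate_reference_chemistry()].
#' @param config a [spectral_model_config()].
#' @return a [spectra_matrix()] with
#'   `nrow(ref) * config$views_per_sample` rows.
#' @export
generate_spectra <- function(ref, config) {
  stopifnot(inherits(config, "spectral_model_config"))
  if (nrow(ref) == 0L) stop_config("reference table is empty")
  wl <- wavelength_grid(config)
  u <- (wl - config$wavelength_min) /
    (config$wavelength_max - config$wavelength_min)
  base <- reflectance_baseline(u)
  # n_bands x n_peaks Gaussian shapes
  shapes <- vapply(seq_along(config$peak_centers), function(k) {
    exp(-0.5 * ((wl - config$peak_centers[k]) / config$peak_widths[k])^2)
  }, numeric(length(wl)))
  analytes <- as.matrix(ref[, c("starch", "vc", "ssc", "ta")])
  depths <- analytes %*% t(config$loading_matrix)      # n_samples x n_peaks
  clean <- matrix(base, nrow(ref), length(wl), byrow = TRUE) -
    depths %*% t(shapes)                                # n_samples x n_bands

  v <- config$views_per_sample
  n <- nrow(ref) * v
  with_seed(config$seed + 1L, {
    slope <- 1 + rnorm(n, sd = config$scatter_slope_sd)
    offset <- rnorm(n, sd = config$scatter_offset_sd)
    rows <- rep(seq_len(nrow(ref)), each = v)
    wiggle <- matrix(0, n, length(wl))
    if (config$wiggle_sd > 0) {
      n_bumps <- 3L
      centers <- matrix(runif(n * n_bumps, config$wavelength_min,
                              config$wavelength_max), n, n_bumps)
      amps <- matrix(rnorm(n * n_bumps, sd = config$wiggle_sd), n, n_bumps)
      for (j in seq_len(n_bumps))
        wiggle <- wiggle + amps[, j] *
          exp(-0.5 * (outer(centers[, j], wl, `-`) /
                        config$wiggle_width)^2)
    }
    out <- clean[rows, , drop = FALSE] * slope + offset + wiggle +
      matrix(rnorm(n * length(wl), sd = config$noise_sd), n, length(wl))
    out[out < 0] <- 0
    out[out > 1] <- 1
    spectra_matrix(out, wl,
                   sample_id = ref$sample_id[rows],
                   view = rep(seq_len(v), nrow(ref)),
                   provenance = list())
  })
}

#' Generate a synthetic raw cube with calibration frames
#'
#' Constructs a dark frame (small positive counts), a near-saturation
#' white frame, and a raw-count cube such that dark/white reflectance
#' correction recovers the input spectrum inside a central "fruit" disk
#' and a flat dim background elsewhere. Optionally plants a bright
#' specular blob inside the fruit to exercise region-growing outlier
#' rejection.
#'
#' @param spectrum reflectance vector in `[0, 1]`, one value per band.
#' @param height,width spatial cube dimensions in pixels (both >= 8).
#' @param seed integer seed.
#' @param noise_sd standard deviation of raw-count noise; `0` gives exact
#'   recovery under reflectance correction.
#' @param specular_blob logical; plant a small near-saturation blob
#'   off-centre inside the fruit disk.
#' @param wavelengths optional wavelength vector for the cube metadata.
#' @return a list with `origin` (a [spectral_cube()] of raw counts),
#'   `frames` (a [calibration_frames()]), `fruit_mask`, `blob_mask`
#'   (logical matrices), and `background` (the background reflectance).
#' @export
generate_cube <- function(spectrum, height = 48, width = 48, seed = 1L,
                          noise_sd = 5, specular_blob = FALSE,
                          wavelengths = NULL) {
  if (height < 8 || width < 8) stop_config("height and width must be >= 8")
  if (any(spectrum < 0 | spectrum > 1))
    stop_config("spectrum values must lie in [0, 1]")
  nb <- length(spectrum)
  if (is.null(wavelengths)) wavelengths <- seq_len(nb)
  background <- 0.05
  rc <- (row(matrix(0, height, width)) - (height + 1) / 2)
  cc <- (col(matrix(0, height, width)) - (width + 1) / 2)
  radius <- 0.38 * min(height, width)
  fruit <- (rc^2 + cc^2) <= radius^2
  blob <- matrix(FALSE, height, width)
  if (specular_blob) {
    br <- max(2, round(radius / 4))
    bc_r <- (height + 1) / 2 - radius / 2
    bc_c <- (width + 1) / 2 + radius / 3
    blob <- ((row(blob) - bc_r)^2 + (col(blob) - bc_c)^2) <= br^2 & fruit
  }
  with_seed(seed, {
    dark <- matrix(100 + abs(rnorm(height * width, sd = 2)), height, width)
    white <- matrix(4000 + rnorm(height * width, sd = 10), height, width)
    refl <- array(background, c(height, width, nb))
    for (b in seq_len(nb)) {
      sl <- refl[, , b]
      sl[fruit] <- spectrum[b]
      sl[blob] <- 0.98
      refl[, , b] <- sl
    }
    raw <- refl * as.vector(white - dark)[
      rep(seq_len(height * width), nb)] + as.vector(dark)
    dim(raw) <- c(height, width, nb)
    if (noise_sd > 0)
      raw <- raw + array(rnorm(length(raw), sd = noise_sd), dim(raw))
    list(origin = spectral_cube(raw, wavelengths, reflectance = FALSE),
         frames = calibration_frames(white, dark),
         fruit_mask = fruit, blob_mask = blob, background = background)
  })
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper producing the reference table and per-view spectra
#' in one call, and optionally the per-sample spectra with views averaged.
#'
#' @param config a [spectral_model_config()].
#' @param aggregate logical; also return view-averaged per-sample spectra.
#' @return list with `reference`, `spectra` (per view) and, if requested,
#'   `spectra_mean` (per sample).
#' @export
generate_dataset <- function(config = spectral_model_config(),
                             aggregate = TRUE) {
  ref <- generate_reference_chemistry(config)
  sp <- generate_spectra(ref, config)
  out <- list(reference = ref, spectra = sp)
  if (aggregate) out$spectra_mean <- aggregate_views(sp)
  out
}

#' Write a reference table or spectra matrix to CSV
#'
#' `write_reference_csv()` writes the reference table with its canonical
#' header; `write_spectra_csv()` writes spectra with a wavelength header
#' row (columns named by wavelength, nm).
#'
#' @param x the object to write.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_reference_csv <- function(x, path) {
  stopifnot(inherits(x, "reference_table"))
  write.csv(as.data.frame(x)[, c("sample_id", "variety", "starch", "vc",
                                 "ssc", "ta")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reference_csv
#' @export
write_spectra_csv <- function(x, path) {
  stopifnot(inherits(x, "spectra_matrix"))
  df <- data.frame(sample_id = x$sample_id, view = x$view, x$values,
                   check.names = FALSE)
  names(df)[-(1:2)] <- format(x$wavelengths, trim = TRUE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a spectra matrix written by [write_spectra_csv()]
#'
#' @param path CSV file path.
#' @return a [spectra_matrix()].
#' @export
read_spectra_csv <- function(path) {
  df <- read.table(path, header = TRUE, sep = ",", check.names = FALSE)
  wl <- as.numeric(names(df)[-(1:2)])
  spectra_matrix(as.matrix(df[, -(1:2), drop = FALSE]), wl,
                 sample_id = df$sample_id, view = df$view)
}
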