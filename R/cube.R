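#' Construct a hyperspectral cube
#'
#' A 3-D array of shape `lines x samples x bands` with its wavelength
#' grid and free-form acquisition metadata (exposure, gain, frame rate,
#' ...). `reflectance = TRUE` marks a calibrated cube.
#'
#' @param values numeric 3-D array, `lines x samples x bands`.
#' @param wavelengths strictly increasing numeric vector, nm, length equal
#'   to the band dimension.
#' @param metadata named list of acquisition metadata (informational).
#' @param reflectance logical flag: calibrated reflectance vs raw counts.
#' @return an object of class `spectral_cube`.
#' @export
spectral_cube <- function(values, wavelengths, metadata = list(),
                          reflectance = FALSE) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop_config("cube values must be a 3-D array (lines x samples x bands)")
  if (length(wavelengths) != dim(values)[3])
    stop_config("wavelength count must equal the band dimension")
  if (is.unsorted(wavelengths, strictly = TRUE))
    stop_config("wavelengths must be strictly increasing")
  if (reflectance && !all(is.finite(values)))
    stop_config("calibrated cube contains non-finite values")
  structure(list(values = values, wavelengths = as.numeric(wavelengths),
                 metadata = metadata, reflectance = isTRUE(reflectance)),
            class = "spectral_cube")
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("spectral_cube: %d lines x %d samples x %d bands (%s)\n",
              d[1], d[2], d[3],
              if (x$reflectance) "reflectance" else "raw counts"))
  invisible(x)
}

#' Dark and white calibration frames
#'
#' @param white 2-D matrix (or 3-D array) of white-reference counts.
#' @param dark same shape, dark-current counts.
#' @return an object of class `calibration_frames`.
#' @export
calibration_frames <- function(white, dark) {
  if (!identical(dim(white), dim(dark)))
    stop_config("white and dark frames must have identical shape")
  structure(list(white = white, dark = dark), class = "calibration_frames")
}

# ENVI data type codes <-> R read/write sizes
.envi_types <- list(`4` = list(what = "numeric", size = 4),
                    `5` = list(what = "numeric", size = 8),
                    `2` = list(what = "integer", size = 2),
                    `12` = list(what = "integer", size = 2),
                    `3` = list(what = "integer", size = 4))

#' Write a cube as an ENVI header + binary pair
#'
#' Writes a plain-text `.hdr` and a flat binary file in the requested
#' interleave. Doubles (data type 5) are the default so write/read
#' round-trips are exact.
#'
#' @param cube a [spectral_cube()].
#' @param path output path; `".hdr"` is appended for the header and the
#'   binary is written to `path` itself.
#' @param interleave one of `"bsq"`, `"bil"`, `"bip"`.
#' @param data_type ENVI data type code (4 = float32, 5 = float64).
#' @return `path`, invisibly.
#' @export
write_envi <- function(cube, path, interleave = c("bsq", "bil", "bip"),
                       data_type = 5) {
  stopifnot(inherits(cube, "spectral_cube"))
  interleave <- match.arg(interleave)
  d <- dim(cube$values)
  tp <- .envi_types[[as.character(data_type)]]
  if (is.null(tp)) stop_config("unsupported ENVI data type ", data_type)
  perm <- switch(interleave,
                 bsq = c(2, 1, 3),   # sample, line, band
                 bil = c(2, 3, 1),   # sample, band, line
                 bip = c(3, 2, 1))   # band, sample, line
  vec <- as.vector(aperm(cube$values, perm))
  con <- file(path, "wb")
  on.exit(close(con))
  if (tp$what == "integer") writeBin(as.integer(round(vec)), con,
                                     size = tp$size, endian = "little")
  else writeBin(as.numeric(vec), con, size = tp$size, endian = "little")
  hdr <- c("ENVI",
           "description = {rotospec cube}",
           sprintf("samples = %d", d[2]),
           sprintf("lines = %d", d[1]),
           sprintf("bands = %d", d[3]),
           "header offset = 0",
           "file type = ENVI Standard",
           sprintf("data type = %d", data_type),
           sprintf("interleave = %s", interleave),
           "byte order = 0",
           sprintf("wavelength units = Nanometers"),
           sprintf("wavelength = {%s}",
                   paste(format(cube$wavelengths, trim = TRUE,
                                digits = 10), collapse = ", ")))
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}

# Parse an ENVI header into a named list; braces may span lines.
parse_envi_header <- function(header_path) {
  txt <- paste(readLines(header_path, warn = FALSE), collapse = "\n")
  out <- list()
  # brace-valued fields
  m <- gregexpr("([a-zA-Z ]+?)\\s*=\\s*\\{([^}]*)\\}", txt)[[1]]
  if (m[1] != -1) {
    for (i in seq_along(m)) {
      s <- substring(txt, m[i], m[i] + attr(m, "match.length")[i] - 1)
      key <- trimws(sub("=.*", "", s))
      val <- sub(".*\\{", "", sub("\\}", "", s))
      out[[tolower(key)]] <- trimws(strsplit(val, ",")[[1]])
    }
  }
  for (line in strsplit(txt, "\n")[[1]]) {
    if (grepl("\\{", line) || !grepl("=", line)) next
    key <- tolower(trimws(sub("=.*", "", line)))
    out[[key]] <- trimws(sub(".*=", "", line))
  }
  out
}

#' Read an ENVI header + binary pair
#'
#' Accepts the header path (`*.hdr`) or the binary path; supports BSQ,
#' BIL and BIP interleaves and data types 2, 3, 4, 5 and 12.
#'
#' @param header_path path to the `.hdr` file (or to the binary, in which
#'   case `.hdr` is appended).
#' @return a [spectral_cube()] (flagged as raw counts; see
#'   [reflectance_correct()]).
#' @export
read_envi <- function(header_path) {
  hdr_file <- if (grepl("\\.hdr$", header_path)) header_path
              else paste0(header_path, ".hdr")
  bin_file <- sub("\\.hdr$", "", hdr_file)
  if (!file.exists(hdr_file)) stop_config("header not found: ", hdr_file)
  if (!file.exists(bin_file)) stop_config("binary not found: ", bin_file)
  h <- parse_envi_header(hdr_file)
  ns <- as.integer(h$samples); nl <- as.integer(h$lines)
  nb <- as.integer(h$bands)
  dtype <- as.character(as.integer(h[["data type"]]))
  interleave <- tolower(h$interleave %||% "bsq")
  tp <- .envi_types[[dtype]]
  if (is.null(tp)) stop_config("unsupported ENVI data type ", dtype)
  offset <- as.integer(h[["header offset"]] %||% "0")
  n_expected <- ns * nl * nb
  actual <- file.info(bin_file)$size - offset
  if (actual != n_expected * tp$size)
    stop_config(sprintf(
      "binary size %d does not match header dimensions %dx%dx%d (%d bytes)",
      actual, nl, ns, nb, n_expected * tp$size))
  con <- file(bin_file, "rb")
  on.exit(close(con))
  if (offset > 0) readBin(con, "raw", offset)
  vec <- readBin(con, tp$what, n = n_expected, size = tp$size,
                 endian = "little")
  dims <- switch(interleave,
                 bsq = c(ns, nl, nb), bil = c(ns, nb, nl),
                 bip = c(nb, ns, nl),
                 stop_config("unsupported interleave ", interleave))
  arr <- array(vec, dims)
  values <- switch(interleave,
                   bsq = aperm(arr, c(2, 1, 3)),
                   bil = aperm(arr, c(3, 1, 2)),
                   bip = aperm(arr, c(3, 2, 1)))
  wl <- if (!is.null(h$wavelength)) as.numeric(h$wavelength)
        else seq_len(nb)
  spectral_cube(values, wl, metadata = h, reflectance = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Dark/white reflectance correction
#'
#' Converts raw counts to relative reflectance using the dark-current and
#' white-reference frames: `R = (R_origin - R_dark) / (R_white - R_dark)`,
#' element-wise, broadcasting 2-D frames across bands. Values outside
#' `[0, 1]` (legitimate on specular pixels) are preserved.
#'
#' @param origin a raw [spectral_cube()].
#' @param frames a [calibration_frames()].
#' @return a [spectral_cube()] flagged as reflectance.
#' @export
reflectance_correct <- function(origin, frames) {
  stopifnot(inherits(origin, "spectral_cube"),
            inherits(frames, "calibration_frames"))
  d <- dim(origin$values)
  w <- frames$white; dk <- frames$dark
  if (length(dim(w)) == 2L) {
    if (!identical(dim(w), d[1:2]))
      stop_config("frame shape does not match cube spatial dimensions")
    denom <- as.vector(w - dk)
    bad <- which(denom == 0)
    if (length(bad))
      stop_config(sprintf(
        "white == dark at pixel (row %d, col %d): cannot correct",
        (bad[1] - 1) %% d[1] + 1, (bad[1] - 1) %/% d[1] + 1))
    vals <- (origin$values - as.vector(dk)) / denom
  } else {
    if (!identical(dim(w), d))
      stop_config("3-D frame shape does not match cube dimensions")
    denom <- w - dk
    bad <- which(denom == 0, arr.ind = TRUE)
    if (nrow(bad))
      stop_config(sprintf(
        "white == dark at pixel (row %d, col %d), band %d",
        bad[1, 1], bad[1, 2], bad[1, 3]))
    vals <- (origin$values - dk) / denom
  }
  spectral_cube(vals, origin$wavelengths, origin$metadata,
                reflectance = TRUE)
}

#' Region-growing extraction of a fruit region of interest
#'
#' Grows a region from a seed point on a single band image: at each of at
#' most `iterations` rounds, the current region's mean and standard
#' deviation are computed once (batch update, so the result is independent
#' of pixel visiting order), and every 4-connected frontier pixel whose
#' value lies within `mean +/- std_multiplier * SD` is admitted. Growth
#' stops at the iteration cap, when no pixel is admitted, or when the
#' region's bounding box reaches `target_size`. The seed's 3x3
#' neighbourhood initialises the region so the SD is defined from the
#' first round.
#'
#' @param band_image 2-D numeric matrix (one band of a cube).
#' @param seed_point integer `(row, col)` inside the image, in a region
#'   unaffected by specular highlights.
#' @param std_multiplier admission half-width in region SDs.
#' @param iterations maximum number of growth rounds.
#' @param target_size integer `(rows, cols)` bounding-box cap.
#' @return an object of class `roi_mask`: list with `mask` (logical
#'   matrix), `seed_point`, `params`, `iterations_run`.
#' @export
region_grow_roi <- function(band_image, seed_point, std_multiplier = 2.2,
                            iterations = 50, target_size = c(480, 480)) {
  band_image <- as.matrix(band_image)
  nr <- nrow(band_image); nc <- ncol(band_image)
  r0 <- seed_point[1]; c0 <- seed_point[2]
  if (r0 < 1 || r0 > nr || c0 < 1 || c0 > nc)
    stop_config("seed point outside image")
  if (length(target_size) == 1L) target_size <- rep(target_size, 2)
  mask <- matrix(FALSE, nr, nc)
  rr <- max(1, r0 - 1):min(nr, r0 + 1)
  cc <- max(1, c0 - 1):min(nc, c0 + 1)
  mask[rr, cc] <- TRUE
  iterations_run <- 0L
  for (it in seq_len(iterations)) {
    vals <- band_image[mask]
    mu <- mean(vals)
    s <- stats::sd(vals)
    if (is.na(s)) s <- 0
    # 4-connected frontier: shift the mask in the four directions
    frontier <- matrix(FALSE, nr, nc)
    frontier[-1, ] <- frontier[-1, ] | mask[-nr, ]
    frontier[-nr, ] <- frontier[-nr, ] | mask[-1, ]
    frontier[, -1] <- frontier[, -1] | mask[, -nc]
    frontier[, -nc] <- frontier[, -nc] | mask[, -1]
    frontier <- frontier & !mask
    admit <- frontier & (abs(band_image - mu) <= std_multiplier * s)
    if (!any(admit)) break
    mask <- mask | admit
    iterations_run <- it
    bb <- which(mask, arr.ind = TRUE)
    if ((max(bb[, 1]) - min(bb[, 1]) + 1) >= target_size[1] ||
        (max(bb[, 2]) - min(bb[, 2]) + 1) >= target_size[2]) break
  }
  structure(list(mask = mask, seed_point = c(r0, c0),
                 params = list(std_multiplier = std_multiplier,
                               iterations = iterations,
                               target_size = target_size),
                 iterations_run = iterations_run),
            class = "roi_mask")
}

#' Mean spectrum over a region of interest
#'
#' Per-band arithmetic mean of all pixels inside the mask.
#'
#' @param cube a [spectral_cube()].
#' @param mask an [region_grow_roi()] result or a logical matrix matching
#'   the cube's spatial dimensions.
#' @return numeric reflectance vector, one value per band.
#' @export
mean_roi_spectrum <- function(cube, mask) {
  stopifnot(inherits(cube, "spectral_cube"))
  m <- if (inherits(mask, "roi_mask")) mask$mask else as.matrix(mask)
  d <- dim(cube$values)
  if (!identical(dim(m), d[1:2]))
    stop_config("mask shape does not match cube spatial dimensions")
  if (!any(m)) stop_config("empty ROI mask")
  idx <- which(m)
  flat <- matrix(cube$values, d[1] * d[2], d[3])
  colMeans(flat[idx, , drop = FALSE])
}

#' Aggregate rotational views into per-sample spectra
#'
#' Element-wise unweighted mean of the view spectra of each sample. Given
#' a [spectra_matrix()], rows are grouped by `sample_id`; given a plain
#' list of equal-length vectors, a single mean spectrum is returned.
#'
#' @param x a [spectra_matrix()] with a `view` column, or a list of
#'   numeric vectors.
#' @return a [spectra_matrix()] with one row per sample (views averaged,
#'   count recorded in provenance), or a numeric vector for list input.
#' @export
aggregate_views <- function(x) {
  if (is.list(x) && !inherits(x, "spectra_matrix")) {
    lens <- lengths(x)
    if (length(unique(lens)) != 1L)
      stop_config("view spectra have unequal lengths")
    return(colMeans(do.call(rbind, x)))
  }
  stopifnot(inherits(x, "spectra_matrix"))
  ids <- unique(x$sample_id)
  out <- t(vapply(ids, function(s) {
    colMeans(x$values[x$sample_id == s, , drop = FALSE])
  }, numeric(ncol(x$values))))
  spectra_matrix(out, x$wavelengths, sample_id = ids,
                 view = rep(1L, length(ids)),
                 provenance = c(x$provenance,
                                list(list(method = "aggregate_views",
                                          params = list(
                                            n_views = nrow(x$values) /
                                              length(ids))))))
}

#' Extract one mean ROI spectrum from a raw cube
#'
#' Convenience chain: reflectance correction, region growing on the band
#' image nearest `roi_band_nm`, then the ROI mean spectrum.
#'
#' @param origin raw [spectral_cube()].
#' @param frames [calibration_frames()].
#' @param seed_point `(row, col)` seed for region growing.
#' @param roi_band_nm wavelength of the band image used for growing
#'   (default 680 nm, the strongest pigment contrast).
#' @param ... passed to [region_grow_roi()].
#' @return list with `spectrum`, `mask`, `cube` (the calibrated cube).
#' @export
extract_sample_spectrum <- function(origin, frames, seed_point,
                                    roi_band_nm = 680, ...) {
  cal <- reflectance_correct(origin, frames)
  b <- which.min(abs(cal$wavelengths - roi_band_nm))
  mask <- region_grow_roi(cal$values[, , b], seed_point, ...)
  list(spectrum = mean_roi_spectrum(cal, mask), mask = mask, cube = cal)
}
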