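# SelectionResult container shared by the three wavelength selectors.

#' Construct a wavelength selection result
#'
#' @param method `"GA"`, `"SPA"` or `"CARS"`.
#' @param indices selected band indices (1-based, unique, sorted).
#' @param n_bands total number of bands selection operated on.
#' @param wavelengths optional wavelength grid (nm) of all bands.
#' @param diagnostics method-specific diagnostics list.
#' @param seed seed used, or `NULL` for deterministic methods.
#' @return an object of class `selection_result` with `n_selected` and
#'   `fraction_of_total` (percent of all bands, 2 decimals) filled in.
#' @export
selection_result <- function(method, indices, n_bands, wavelengths = NULL,
                             diagnostics = list(), seed = NULL) {
  indices <- sort(unique(as.integer(indices)))
  if (any(indices < 1L | indices > n_bands))
    stop_config("indices out of band range")
  structure(list(method = method,
                 indices = indices,
                 wavelengths = if (!is.null(wavelengths))
                   wavelengths[indices],
                 n_selected = length(indices),
                 n_bands = as.integer(n_bands),
                 fraction_of_total = fraction_of_total(length(indices),
                                                       n_bands),
                 diagnostics = diagnostics,
                 seed = seed),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("%s selection: %d of %d bands (%.2f%%)\n", x$method,
              x$n_selected, x$n_bands, x$fraction_of_total))
  invisible(x)
}

#' Serialize a selection result to JSON
#'
#' @param x a [selection_result()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_selection_json <- function(x, path) {
  stopifnot(inherits(x, "selection_result"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

# Pull the numeric matrix + response out of heterogeneous inputs.
selector_inputs <- function(X, y) {
  M <- if (inherits(X, "spectra_matrix")) X$values else as.matrix(X)
  y <- as.numeric(y)
  if (length(y) == 0L) stop_config("empty response vector")
  if (nrow(M) != length(y)) stop_config("X rows must match length(y)")
  wl <- if (inherits(X, "spectra_matrix")) X$wavelengths
        else seq_len(ncol(M))
  list(X = M, y = y, wavelengths = wl)
}
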