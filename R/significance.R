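#' Significance of MLR coefficients on selected bands
#'
#' Ordinary least squares of the response on the selected-band spectra,
#' with per-coefficient standard errors from the residual variance times
#' the diagonal of the inverse normal-equations matrix, t statistics,
#' and two-sided p-values on `n - k - 1` degrees of freedom. A band is
#' flagged significant when `|t| > t_threshold` or `p < p_threshold`
#' (the two sub-rules differ slightly at small n, so both are reported
#' alongside the combined flag). No multiple-testing correction is
#' applied by default; `adjust = "BH"` adds a Benjamini-Hochberg
#' adjusted column and bases the p sub-rule on it.
#'
#' @param X_selected matrix (or [spectra_matrix()]) restricted to the
#'   selected bands; samples in rows.
#' @param y numeric response.
#' @param wavelengths optional per-column wavelengths (nm); taken from a
#'   [spectra_matrix()] input automatically.
#' @param analyte optional label for the response.
#' @param t_threshold,p_threshold significance rule parameters.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return an object of class `significance_report`: a list with `table`
#'   (one row per band: index, wavelength, coefficient, standard error,
#'   t and p values, the two sub-flags, `significant`), the intercept
#'   row, `analyte`, `rule`, and the degrees of freedom.
#' @export
mlr_significance <- function(X_selected, y, wavelengths = NULL,
                             analyte = NULL, t_threshold = 2,
                             p_threshold = 0.05,
                             adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (inherits(X_selected, "spectra_matrix")) {
    if (is.null(wavelengths)) wavelengths <- X_selected$wavelengths
    X_selected <- X_selected$values
  }
  M <- as.matrix(X_selected)
  y <- as.numeric(y)
  n <- nrow(M)
  k <- ncol(M)
  if (n != length(y)) stop_config("X rows must match length(y)")
  if (n <= k + 1)
    stop_config("need n_samples > n_features + 1 for coefficient tests")
  D <- cbind(`(Intercept)` = 1, M)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    drop_cols <- qrD$pivot[(qrD$rank + 1):ncol(D)] - 1L
    stop_config("singular design: collinear bands at columns ",
                paste(drop_cols, collapse = ", "))
  }
  beta <- qr.coef(qrD, y)
  res <- y - drop(D %*% beta)
  df <- n - k - 1L
  s2 <- sum(res^2) / df
  XtX_inv <- chol2inv(chol(crossprod(D)))
  se <- sqrt(s2 * diag(XtX_inv))
  tval <- beta / se
  pval <- 2 * pt(-abs(tval), df)
  p_used <- if (adjust == "BH") stats::p.adjust(pval[-1], "BH")
            else pval[-1]
  wl <- if (is.null(wavelengths)) rep(NA_real_, k) else wavelengths
  tab <- data.frame(band = seq_len(k),
                    wavelength = wl,
                    coefficient = beta[-1],
                    std_error = se[-1],
                    t_value = tval[-1],
                    p_value = pval[-1],
                    sig_t = abs(tval[-1]) > t_threshold,
                    sig_p = p_used < p_threshold,
                    row.names = NULL)
  if (adjust == "BH") tab$p_adjusted <- p_used
  tab$significant <- tab$sig_t | tab$sig_p
  structure(list(table = tab,
                 intercept = c(coefficient = unname(beta[1]),
                               std_error = unname(se[1]),
                               t_value = unname(tval[1]),
                               p_value = unname(pval[1])),
                 analyte = analyte,
                 rule = list(t_threshold = t_threshold,
                             p_threshold = p_threshold, adjust = adjust),
                 df = df),
            class = "significance_report")
}

#' @export
print.significance_report <- function(x, ...) {
  cat(sprintf("significance of %d bands%s: %d flagged (|t| > %g or p < %g)\n",
              nrow(x$table),
              if (!is.null(x$analyte)) paste0(" [", x$analyte, "]") else "",
              sum(x$table$significant), x$rule$t_threshold,
              x$rule$p_threshold))
  invisible(x)
}

#' Overlap of significant bands between two analytes
#'
#' Compares the significant wavelength sets of two significance reports
#' and summarises how much of each falls inside a wavelength window
#' (e.g. the 470-700 nm pigment-absorption region shared by starch and
#' vitamin C).
#'
#' @param report_a,report_b [mlr_significance()] results with
#'   wavelengths available.
#' @param window numeric `(min, max)` wavelength interval, nm.
#' @return list with the two significant sets (`bands_a`, `bands_b`,
#'   wavelengths in nm), their `intersection`, and
#'   `fraction_in_window_a` / `fraction_in_window_b` (`NaN` when a set
#'   is empty).
#' @export
band_overlap <- function(report_a, report_b, window = c(470, 700)) {
  stopifnot(inherits(report_a, "significance_report"),
            inherits(report_b, "significance_report"))
  sig_wl <- function(r) r$table$wavelength[r$table$significant]
  a <- sig_wl(report_a)
  b <- sig_wl(report_b)
  in_win <- function(w) w >= window[1] & w <= window[2]
  list(bands_a = a, bands_b = b,
       intersection = intersect(a, b),
       fraction_in_window_a = mean(in_win(a)),
       fraction_in_window_b = mean(in_win(b)),
       window = window)
}

#' Write a significance report as CSV
#'
#' @param x a `significance_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_significance_csv <- function(x, path) {
  stopifnot(inherits(x, "significance_report"))
  write.csv(x$table, path, row.names = FALSE)
  invisible(path)
}
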