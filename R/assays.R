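# Wet-chemistry computation formulas for the three titration-based
# reference assays, as pure functions of the bench readings. (Soluble
# solids is a direct refractometer reading and needs no formula.)

check_positive <- function(...) {
  args <- list(...)
  bad <- names(args)[vapply(args, function(v) any(v <= 0), logical(1))]
  if (length(bad))
    stop_config("non-positive value for ", paste(bad, collapse = ", "))
}

#' Vitamin C content from dye titration
#'
#' `VC (per mille) = (v3 - v2) * d / m * vt / vs * 100`, the
#' 2,6-dichlorophenol-indophenol titration formula.
#'
#' @param v3,v2 dye volume (mL) used to titrate the sample and the
#'   blank.
#' @param d titer degree of the dye (mass of ascorbic acid per mL dye).
#' @param m sample mass (g).
#' @param vt total volume of the extracted sample solution (mL).
#' @param vs volume of extract used in the titration (mL).
#' @return vitamin C content, per mille.
#' @export
#' @examples
#' vc_content(v3 = 3, v2 = 2, d = 1, m = 100, vt = 50, vs = 50)
vc_content <- function(v3, v2, d, m, vt, vs) {
  check_positive(m = m, vs = vs, vt = vt)
  (v3 - v2) * d / m * vt / vs * 100
}

#' Titratable acid content from alkali titration
#'
#' `TA (per mille) = c * (v1 - v0) * k * F / m * 1000`.
#'
#' @param c concentration of the sodium hydroxide standard solution
#'   (mol/L).
#' @param v1,v0 NaOH volume (mL) consumed titrating the sample and the
#'   blank.
#' @param k acid conversion factor (g acid per mmol NaOH; 0.067 for
#'   malic acid).
#' @param m specimen mass (g).
#' @param F dilution/scale factor of the extract (default 1).
#' @return titratable acid content, per mille.
#' @export
#' @examples
#' ta_content(c = 0.1, v1 = 12, v0 = 10, k = 0.067, m = 10)
ta_content <- function(c, v1, v0, k, m, F = 1) {
  check_positive(m = m)
  c * (v1 - v0) * k * F / m * 1000
}

#' Starch content from hydrolysed-sugar assay
#'
#' `Starch (%) = c * vt / v * d / m * 0.9`, with 0.9 the fixed
#' starch-hydrolysis correction factor (glucose to starch mass ratio).
#'
#' @param c sugar content of the assayed aliquot (mg, from the glucose
#'   standard curve).
#' @param vt total extract volume (mL).
#' @param v assay volume (mL).
#' @param d number of dilutions.
#' @param m sample mass (g).
#' @return starch content, percent.
#' @export
#' @examples
#' starch_content(c = 10, vt = 5, v = 5, d = 1, m = 9)
starch_content <- function(c, vt, v, d, m) {
  check_positive(m = m, v = v)
  c * vt / v * d / m * 0.9
}
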