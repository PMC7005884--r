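#' Physical and unit constants
#'
#' Single source of truth for unit conversions and isotope baselines used
#' throughout the package.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{fg_per_fmol_N}{14 fg nitrogen per fmol.}
#'   \item{fg_per_fmol_C}{12 fg carbon per fmol.}
#'   \item{fmol_per_nmol}{1e6 fmol per nmol.}
#'   \item{R_kJ}{Gas constant, kJ mol^-1 K^-1.}
#'   \item{redfield_cn}{Canonical marine biomass C:N molar ratio 106:16 = 6.625.}
#' }
#' @export
sip_constants <- list(
  fg_per_fmol_N = 14,
  fg_per_fmol_C = 12,
  fmol_per_nmol = 1e6,
  R_kJ          = 8.31446261815324e-3,
  redfield_cn   = 6.625
)

#' Natural-abundance isotope baselines
#'
#' Atom fractions of the rare isotope at natural abundance: 0.37% for 15N and
#' 1.11% for 13C. These are the baselines subtracted when converting measured
#' atom fractions to atom-percent excess.
#'
#' @param n15 Natural 15N atom fraction (default 0.0037).
#' @param c13 Natural 13C atom fraction (default 0.0111).
#' @return An object of class `natural_abundance`: a named list with
#'   `n15_fraction` and `c13_fraction`.
#' @examples
#' natural_abundance()
#' @export
natural_abundance <- function(n15 = 0.0037, c13 = 0.0111) {
  stopifnot(n15 >= 0, n15 < 1, c13 >= 0, c13 < 1)
  structure(list(n15_fraction = n15, c13_fraction = c13),
            class = "natural_abundance")
}

# baseline atom fraction for an element, from a natural_abundance object
.baseline_fraction <- function(baseline, element = c("N", "C")) {
  element <- match.arg(element)
  if (element == "N") baseline$n15_fraction else baseline$c13_fraction
}
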