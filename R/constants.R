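#' Physical constants used throughout the pipeline
#'
#' Monoisotopic element masses (IUPAC/CODATA), the proton mass used for
#' \eqn{[M-H]^-} neutralization, the \eqn{^{13}C-^{12}C} isotopologue spacing,
#' and the exact masses of the CH2 and C4H2 repeat units.
#'
#' These must stay in sync with the element masses compiled into the C++
#' enumerator (src/enumerate.cpp).
#'
#' @format A named numeric vector.
#' @keywords internal
#' @name pyrodom-constants
NULL

.ELEMENT_MASS <- c(
  C = 12.000000,
  H = 1.00782503,
  N = 14.00307401,
  O = 15.99491462,
  P = 30.97376163,
  S = 31.97207117
)

.PROTON_MASS <- 1.00727646

# 13C - 12C mass difference (Da); spacing of the single-13C satellite
.C13_SPACING <- 1.0033548

.MASS_CH2  <- 12.000000 + 2 * 1.00782503   # 14.01565006
.MASS_C4H2 <- 48.000000 + 2 * 1.00782503   # 50.01565006

# exact mass of C4H2 as printed in some KMD applications (see kendrickConfig)
.MASS_C4H2_PRINTED <- 50.0587

#' Element masses and ion-chemistry constants
#'
#' Accessors for the monoisotopic masses the package computes with, so user
#' code and tests never hard-code them independently.
#'
#' @return `elementMasses()` returns the named vector of monoisotopic masses
#'   for C, H, N, O, P, S; `protonMass()` the proton mass in Da;
#'   `isotopologueSpacing()` the 13C-12C spacing in Da.
#' @examples
#' elementMasses()[["O"]]
#' protonMass()
#' @export
elementMasses <- function() .ELEMENT_MASS

#' @rdname elementMasses
#' @export
protonMass <- function() .PROTON_MASS

#' @rdname elementMasses
#' @export
isotopologueSpacing <- function() .C13_SPACING
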