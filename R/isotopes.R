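# Isotope masses (Da) and natural abundances pinned in-repo so that results
# do not drift with external library versions. Monoisotopic masses from the
# AME2020 atomic mass evaluation; representative natural abundances from the
# IUPAC-CIAAW 2021 tables. Stated to >= 6 decimals.

ELEMENTS <- c("C", "H", "N", "O", "P", "S")

.ISOTOPES <- list(
  C = list(mass = c(12.0, 13.0033548351),
           abundance = c(0.9893, 0.0107)),
  H = list(mass = c(1.0078250319, 2.0141017781),
           abundance = c(0.999885, 0.000115)),
  N = list(mass = c(14.0030740044, 15.0001088989),
           abundance = c(0.99636, 0.00364)),
  O = list(mass = c(15.9949146196, 16.9991317565, 17.9991596129),
           abundance = c(0.99757, 0.00038, 0.00205)),
  P = list(mass = 30.9737619984,
           abundance = 1.0),
  S = list(mass = c(31.9720711744, 32.9714589098, 33.9678670040, 35.9670807100),
           abundance = c(0.9499, 0.0075, 0.0425, 0.0001))
)

ELEMENT_MASS <- vapply(.ISOTOPES, function(x) x$mass[1L], numeric(1))[ELEMENTS]

ELECTRON_MASS <- 0.000548579909

# Singly charged positive adducts supported in positive-mode DI-nESI.
# Ion m/z = neutral monoisotopic mass + adduct atom mass - electron mass.
ADDUCT_MASS <- c("[M+H]+"  = 1.0078250319,
                 "[M+Na]+" = 22.9897692820,
                 "[M+K]+"  = 38.9637064864)

# Spacing used to locate M+1 isotopologue partners of a peak; the 13C-12C
# mass difference, which dominates the M+1 shell of CHNOPS metabolites.
ISO_UNIT <- 13.0033548351 - 12.0

#' Isotope mass and abundance table
#'
#' Returns the isotope table the package is pinned to, one row per isotope
#' of the supported elements C, H, N, O, P and S.
#'
#' @return A data.frame with columns `element`, `mass` (Da) and `abundance`
#'   (fraction), ordered by element then mass.
#' @export
#' @examples
#' isotope_table()
isotope_table <- function() {
  do.call(rbind, lapply(ELEMENTS, function(e) {
    data.frame(element = e, mass = .ISOTOPES[[e]]$mass,
               abundance = .ISOTOPES[[e]]$abundance)
  }))
}

#' Supported adducts
#'
#' @return Named numeric vector of adduct atom masses (Da) for the supported
#'   singly charged positive adducts.
#' @export
adducts <- function() ADDUCT_MASS
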