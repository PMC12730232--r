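#' Monoisotopic element masses and fundamental constants
#'
#' Masses (in Da) of the elements occurring in membrane lipids and their
#' common adducts, plus the proton and electron masses and the isotope
#' shifts used for stable-isotope label bookkeeping.
#'
#' @return Named numeric vector of monoisotopic masses in Da.
#' @export
#' @examples
#' element_masses()[["C"]]
element_masses <- function() {
  c(
    C  = 12.000000,
    H  = 1.00782503,
    N  = 14.0030740,
    O  = 15.9949146,
    P  = 30.9737615,
    S  = 31.9720707,
    Na = 22.9897693,
    K  = 38.9637065
  )
}

#' @rdname element_masses
#' @format NULL
#' @export
MASS_PROTON <- 1.00727646

#' @rdname element_masses
#' @format NULL
#' @export
MASS_ELECTRON <- 0.00054858

#' Isotope mass shifts
#'
#' Mass difference between the heavy isotope and the most abundant one:
#' 13C - 12C and 15N - 14N, in Da. These are the per-atom shifts applied
#' when a species carries a stable-isotope label.
#'
#' @export
SHIFT_13C <- 1.0033548

#' @rdname SHIFT_13C
#' @export
SHIFT_15N <- 0.9970349

#' Mass of a water molecule (for [M+H-H2O]+ ions), Da.
#' @export
MASS_H2O <- 18.010565

# Named neutral losses used in printed assignments: the serine headgroup
# fragment lost from PS ("-87") and trimethylamine lost from PC ("-TMA").
neutral_loss_formulas <- function() {
  list(
    serine = c(C = 3L, H = 5L, N = 1L, O = 2L),
    TMA    = c(C = 3L, H = 9L, N = 1L)
  )
}
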