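#' Fraction-to-mass calibration of a separation gradient
#'
#' Non-denaturing separations (size-exclusion chromatography, blue-native
#' PAGE) resolve assemblies by molecular mass, and collected fractions map
#' onto that mass scale approximately log-linearly. A calibration fixes the
#' mass at the first and last analysed fraction and interpolates
#' `log10(mass)` linearly in between. The default spans 2 MDa at fraction 1
#' down to 100 kDa at fraction 55, the working range of a 55-fraction
#' complexome separation.
#'
#' @param n_fractions Number of fractions spanning the calibrated range.
#' @param mw_first Molecular mass (Da) eluting at fraction 1. Must exceed
#'   `mw_last`.
#' @param mw_last Molecular mass (Da) eluting at the final fraction.
#'
#' @return An object of class `mass_calibration`.
#' @examples
#' cal <- mass_calibration()
#' fraction_for_mass(cal, 4.47e5)
#' @export
mass_calibration <- function(n_fractions = 55, mw_first = 2e6, mw_last = 1e5) {
  stopifnot(n_fractions >= 2)
  if (!(mw_first > mw_last && mw_last > 0)) {
    stop_cofrac("`mw_first` must exceed `mw_last`, and both must be positive",
                "cofrac_calibration_error")
  }
  structure(
    list(n_fractions = as.integer(n_fractions),
         mw_first = mw_first, mw_last = mw_last),
    class = "mass_calibration"
  )
}

#' @export
print.mass_calibration <- function(x, ...) {
  cat(sprintf("<mass_calibration> %d fractions: %.3g Da (f=1) to %.3g Da (f=%d)\n",
              x$n_fractions, x$mw_first, x$mw_last, x$n_fractions))
  invisible(x)
}

#' Convert an assembly mass to its elution fraction
#'
#' Interpolates `log10(mass)` linearly between the calibrated endpoints.
#' Masses outside the calibrated range are clamped to the nearest endpoint
#' with a warning, mirroring how species larger than the exclusion limit
#' elute in the void volume.
#'
#' @param cal A [mass_calibration()].
#' @param mass Molecular mass in Da (vectorised).
#' @param extrapolate If `TRUE`, masses outside the calibrated range map
#'   to fraction positions beyond the `1..F` axis by the same log-linear
#'   rule (species lighter than `mw_last` elute after the last analysed
#'   fraction); if `FALSE` (default) they are clamped with a warning.
#' @return Real-valued fraction positions, between 1 and `cal$n_fractions`
#'   unless `extrapolate = TRUE`.
#' @export
fraction_for_mass <- function(cal, mass, extrapolate = FALSE) {
  stopifnot(inherits(cal, "mass_calibration"))
  out_of_range <- mass > cal$mw_first | mass < cal$mw_last
  if (any(out_of_range) && !extrapolate) {
    warn(sprintf("%d mass value(s) outside the calibrated range were clamped",
                 sum(out_of_range)))
    mass <- pmin(pmax(mass, cal$mw_last), cal$mw_first)
  }
  lo <- log10(cal$mw_first)
  hi <- log10(cal$mw_last)
  1 + (log10(mass) - lo) / (hi - lo) * (cal$n_fractions - 1)
}

#' Invert a calibration: fraction position to molecular mass
#'
#' @inheritParams fraction_for_mass
#' @param fraction Real-valued fraction positions.
#' @return Molecular masses in Da.
#' @export
mass_for_fraction <- function(cal, fraction) {
  stopifnot(inherits(cal, "mass_calibration"))
  lo <- log10(cal$mw_first)
  hi <- log10(cal$mw_last)
  10^(lo + (fraction - 1) / (cal$n_fractions - 1) * (hi - lo))
}
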