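#' Convert a volumetric process rate to an epilimnetic-sediment-area basis
#'
#' Multiplies a water-column rate (per m^3 of epilimnetic water) by the
#' composite mean epilimnion thickness \eqn{V_{EpiC}/A_{EpiC}} (m^3 m^-2)
#' to express it per m^2 of epilimnetic sediment surface.
#'
#' @param rate_v Volumetric rate (amount m^-3 d^-1).
#' @param epi_ratio \eqn{V_{EpiC}/A_{EpiC}} (m^3 m^-2), positive; NA
#'   (undefined for a fully isolated composite) propagates.
#' @return Areal rate (amount m^-2 d^-1).
#' @export
volumetric_to_areal <- function(rate_v, epi_ratio) {
  if (any(is.finite(epi_ratio) & epi_ratio <= 0))
    stop("epi_ratio must be positive")
  rate_v * epi_ratio
}

#' Express a volumetric rate per unit composite lake surface area
#'
#' \code{rate_v * epi_ratio * fa_epi}: the sediment-area rate of
#' \code{\link{volumetric_to_areal}} scaled by the fraction of epilimnetic
#' sediment surface area, giving the rate per m^2 of lake surface.
#'
#' @inheritParams volumetric_to_areal
#' @param fa_epi Fraction of epilimnetic sediment surface area, in [0, 1].
#' @return Rate per m^2 of composite lake surface.
#' @export
per_lake_surface <- function(rate_v, epi_ratio, fa_epi) {
  if (any(fa_epi < 0 | fa_epi > 1, na.rm = TRUE))
    stop("fa_epi must be in [0, 1]")
  volumetric_to_areal(rate_v, epi_ratio) * fa_epi
}

#' Epilimnetic water volume per square metre of lake surface
#'
#' \code{fa_epi * epi_ratio} (m^3 m^-2): the average volume of epilimnetic
#' water above each square metre of lake surface. The companion
#' \code{sediment_matching_factor} is the factor by which an area-based
#' process rate in the epilimnetic sediments must exceed a volume-based
#' rate in the water column to match its whole-system influence; it equals
#' the \eqn{V_{EpiC}/A_{EpiC}} ratio itself.
#'
#' @inheritParams per_lake_surface
#' @return Named list: \code{water_m3_per_m2} and
#'   \code{sediment_matching_factor}.
#' @export
epilimnetic_water_per_m2 <- function(fa_epi, epi_ratio) {
  if (any(fa_epi < 0 | fa_epi > 1, na.rm = TRUE))
    stop("fa_epi must be in [0, 1]")
  list(water_m3_per_m2 = fa_epi * epi_ratio,
       sediment_matching_factor = epi_ratio)
}

#' First-order ratio of two process rates
#'
#' Plain quotient used to compare an average volumetric water-column rate
#' with an areal sediment rate. The operands carry different units
#' (per m^3 vs per m^2), so the result is a first-order comparison value
#' only; the returned object is flagged accordingly.
#'
#' @param rate_a,rate_b Positive rates; \code{rate_a} may be 0.
#' @return The quotient with attribute \code{"unit_consistent" = FALSE}.
#' @export
rate_ratio <- function(rate_a, rate_b) {
  if (any(rate_b == 0)) stop("zero denominator rate")
  if (any(rate_a < 0 | rate_b < 0)) stop("rates must be non-negative")
  structure(rate_a / rate_b, unit_consistent = FALSE)
}
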