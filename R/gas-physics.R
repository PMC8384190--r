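#' Dissolved-oxygen saturation concentration in fresh water
#'
#' Garcia and Gordon (1992) fit to the Benson–Krause data, evaluated for zero
#' salinity and scaled linearly by barometric pressure. This is the
#' equilibrium concentration a stream relaxes toward through gas exchange.
#'
#' @param temp Water temperature, degrees C. Must lie in \[-2, 40\].
#' @param pressure_atm Barometric pressure in atmospheres (default 1).
#' @return Saturation DO in mg L^-1, same length as `temp`.
#' @examples
#' o2_saturation(20) # about 9.1 mg/L
#' @export
o2_saturation <- function(temp, pressure_atm = 1) {
  if (any(!is.finite(temp))) stop("non-finite temperature")
  if (any(temp < -2 | temp > 40))
    stop("temperature outside [-2, 40] degC: ", paste(range(temp), collapse = ", "))
  ts <- log((298.15 - temp) / (273.15 + temp))
  lnc <- 2.00907 + 3.22014 * ts + 4.05010 * ts^2 + 4.94457 * ts^3 -
    0.256847 * ts^4 + 3.88767 * ts^5
  # exp(lnc) is mL/L at 1 atm; 1.42905 mg O2 per mL O2 (STP)
  exp(lnc) * 1.42905 * pressure_atm
}

#' Schmidt number for oxygen in fresh water
#'
#' Wanninkhof (1992) polynomial; Sc(20 degC) is close to 530.
#'
#' @param temp Water temperature, degrees C.
#' @return Dimensionless Schmidt number.
#' @export
schmidt_o2 <- function(temp) {
  1800.6 - 120.10 * temp + 3.7818 * temp^2 - 0.047608 * temp^3
}

#' Convert K600 to the oxygen-specific gas-exchange rate
#'
#' Standard Schmidt-number scaling with exponent -1/2 appropriate for
#' turbulent streams: `k_O2 = K600 * (Sc_O2 / 600)^(-1/2)`.
#'
#' @param k600 Gas-exchange rate normalised to Schmidt number 600, d^-1.
#' @param temp Water temperature, degrees C.
#' @return Oxygen-specific exchange rate, d^-1.
#' @export
k600_to_ko2 <- function(k600, temp) {
  if (any(k600 < 0)) stop("k600 must be >= 0")
  k600 * (schmidt_o2(temp) / 600)^(-0.5)
}
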