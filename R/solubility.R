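#' Oxygen solubility at 100% air saturation
#'
#' Dissolved-oxygen concentration of air-equilibrated water (mg O2 per litre)
#' as a function of temperature and salinity, from the Garcia & Gordon (1992)
#' combined-fit coefficients (ml O2 l-1), converted to mass units with
#' 1.42905 mg per ml O2 at STP. This is the beta term used to convert a
#' percent-air-saturation decline into an oxygen mass flux.
#'
#' @param temperature_c Water temperature in degrees Celsius, in \[-2, 40\].
#' @param salinity_ppt Practical salinity in parts per thousand, in \[0, 40\].
#'
#' @return Solubility in mg O2 per litre at 100% air saturation. Vectorised
#'   over both arguments.
#'
#' @details Solubility decreases monotonically with both temperature and
#'   salinity over the supported range. At 10 degrees C in fresh water the
#'   value is approximately 11.3 mg l-1.
#'
#' @examples
#' oxygen_solubility(10, 0)    # ~11.29 mg/l, fresh water
#' oxygen_solubility(10, 33)   # ~9.14 mg/l, sea water
#' @export
oxygen_solubility <- function(temperature_c, salinity_ppt) {
  if (any(!is.finite(temperature_c)) || any(!is.finite(salinity_ppt))) {
    stop("temperature and salinity must be finite", call. = FALSE)
  }
  if (any(temperature_c < -2 | temperature_c > 40)) {
    stop("temperature out of supported range [-2, 40] degrees C", call. = FALSE)
  }
  if (any(salinity_ppt < 0 | salinity_ppt > 40)) {
    stop("salinity out of supported range [0, 40] ppt", call. = FALSE)
  }
  # Garcia & Gordon (1992) combined fit, units ml O2 / l
  a <- c(2.00907, 3.22014, 4.05010, 4.94457, -2.56847e-1, 3.88767)
  b <- c(-6.24523e-3, -7.37614e-3, -1.03410e-2, -8.17083e-3)
  c0 <- -4.88682e-7
  ts <- log((298.15 - temperature_c) / (273.15 + temperature_c))
  ln_c <- a[1] + a[2] * ts + a[3] * ts^2 + a[4] * ts^3 + a[5] * ts^4 +
    a[6] * ts^5 +
    salinity_ppt * (b[1] + b[2] * ts + b[3] * ts^2 + b[4] * ts^3) +
    c0 * salinity_ppt^2
  exp(ln_c) * 1.42905
}
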