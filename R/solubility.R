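# Dissolved-oxygen solubility in freshwater at standard pressure (101.325 kPa).
# Benson & Krause equilibrium saturation equation, the formulation behind the
# standard dissolved-oxygen saturation tables used in water-quality work.

#' Oxygen saturation concentration in freshwater
#'
#' Equilibrium dissolved-oxygen concentration of air-saturated freshwater at
#' standard atmospheric pressure, from the Benson-Krause equation. Salinity is
#' fixed at zero (freshwater trials).
#'
#' @param temp_C Water temperature in degrees Celsius. Valid from 0 to 40.
#' @return Saturation concentration in mg O2 per litre.
#' @export
#' @examples
#' o2_sat_mgL(10) # about 11.29 mg/L
o2_sat_mgL <- function(temp_C) {
  if (any(!is.finite(temp_C))) stop("temp_C must be finite")
  if (any(temp_C < 0 | temp_C > 40)) {
    stop("temp_C outside the 0-40 degC validity range of the solubility equation")
  }
  tk <- temp_C + 273.15
  exp(-139.34411 + 1.575701e5 / tk - 6.642308e7 / tk^2 +
        1.2438e10 / tk^3 - 8.621949e11 / tk^4)
}

#' Convert percent air saturation to mg O2 per litre
#'
#' @param o2_pct Dissolved oxygen as percent air saturation (100 = equilibrium
#'   with air; hyperoxic water exceeds 100).
#' @param temp_C Water temperature in degrees Celsius.
#' @return Concentration in mg O2 per litre.
#' @seealso [mgL_to_airsat()] for the inverse.
#' @export
airsat_to_mgL <- function(o2_pct, temp_C) {
  (o2_pct / 100) * o2_sat_mgL(temp_C)
}

#' Convert mg O2 per litre to percent air saturation
#'
#' @param mgL Concentration in mg O2 per litre.
#' @param temp_C Water temperature in degrees Celsius.
#' @return Percent air saturation.
#' @export
mgL_to_airsat <- function(mgL, temp_C) {
  100 * mgL / o2_sat_mgL(temp_C)
}
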