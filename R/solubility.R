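# Oxygen solubility and seawater density at atmospheric pressure.
# Needed to express optode readings (% air saturation) as volumetric
# concentrations so that O2 rate images come out in umol O2 L^-1 min^-1.

#' O2 saturation concentration in seawater (umol per kg)
#'
#' Garcia & Gordon (1992) combined fit to the Benson & Krause data:
#' the equilibrium O2 concentration of air-saturated seawater at one
#' atmosphere. Published check value: 274.610 umol/kg at T = 10 C, S = 35.
#'
#' @param temp_c Temperature in degrees C, valid -2..40.
#' @param salinity Practical salinity, valid 0..42.
#' @return O2 saturation concentration in umol per kg seawater.
#' @export
o2_saturation_umol_kg <- function(temp_c, salinity) {
  check_ts(temp_c, salinity)
  ts <- log((298.15 - temp_c) / (273.15 + temp_c))
  A <- c(5.80871, 3.20291, 4.17887, 5.10006, -9.86643e-2, 3.80369)
  B <- c(-7.01577e-3, -7.70028e-3, -1.13864e-2, -9.51519e-3)
  C0 <- -2.75915e-7
  lnc <- A[1] + A[2] * ts + A[3] * ts^2 + A[4] * ts^3 + A[5] * ts^4 +
    A[6] * ts^5 +
    salinity * (B[1] + B[2] * ts + B[3] * ts^2 + B[4] * ts^3) +
    C0 * salinity^2
  exp(lnc)
}

#' Seawater density at atmospheric pressure (kg per m3)
#'
#' Millero & Poisson (1981) one-atmosphere equation of state. Published
#' check value: 1027.67547 kg/m3 at T = 5 C, S = 35.
#'
#' @inheritParams o2_saturation_umol_kg
#' @return Density in kg per m3.
#' @export
seawater_density <- function(temp_c, salinity) {
  check_ts(temp_c, salinity)
  t <- temp_c
  rw <- 999.842594 + 6.793952e-2 * t - 9.095290e-3 * t^2 +
    1.001685e-4 * t^3 - 1.120083e-6 * t^4 + 6.536332e-9 * t^5
  A <- 0.824493 - 4.0899e-3 * t + 7.6438e-5 * t^2 - 8.2467e-7 * t^3 +
    5.3875e-9 * t^4
  B <- -5.72466e-3 + 1.0227e-4 * t - 1.6546e-6 * t^2
  rw + A * salinity + B * salinity^1.5 + 4.8314e-4 * salinity^2
}

#' Convert % air saturation to volumetric O2 concentration
#'
#' `conc = (c/100) * Csat(T, S) * rho(T, S)`, with the saturation
#' concentration from [o2_saturation_umol_kg()] and density from
#' [seawater_density()]. Defaults match the experimental conditions
#' (23 C, salinity 35), at which air saturation corresponds to
#' about 219 umol O2 per litre.
#'
#' @param c_airsat O2 in % air saturation (scalar, vector or matrix).
#' @param temp_c Temperature in degrees C (default 23).
#' @param salinity Practical salinity (default 35).
#' @return O2 concentration in umol per litre, same shape as `c_airsat`.
#' @export
airsat_to_concentration <- function(c_airsat, temp_c = 23, salinity = 35) {
  csat <- o2_saturation_umol_kg(temp_c, salinity)       # umol/kg
  rho <- seawater_density(temp_c, salinity) / 1000      # kg/L
  (c_airsat / 100) * csat * rho
}

check_ts <- function(temp_c, salinity) {
  if (!is.finite(temp_c) || temp_c < -2 || temp_c > 40) {
    stop("temperature out of range [-2, 40] C: ", temp_c)
  }
  if (!is.finite(salinity) || salinity < 0 || salinity > 42) {
    stop("salinity out of range [0, 42]: ", salinity)
  }
  invisible(TRUE)
}
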