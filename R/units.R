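#' Physical constants and unit conversions
#'
#' Small helpers shared by the climate and crop modules: psychrometrics,
#' CO2 ppm to mass conversion, and the PAR conversion used throughout.
#'
#' @name units
NULL

# fraction of global (shortwave) radiation that is PAR, and the
# energy-to-photon conversion for sunlight. Standard horticultural constants.
PAR_FRACTION <- 0.47
PAR_UMOL_PER_J <- 4.6

# latent heat of vaporisation of water, J per g (at ~20 degC)
LATENT_HEAT_VAPOUR <- 2450

# specific heat capacity of air, J/kg/K, and density at ~20 degC, kg/m3
CP_AIR <- 1006
RHO_AIR <- 1.20

R_GAS <- 8.314      # J/mol/K
M_CO2 <- 44.01      # g/mol
M_H2O <- 18.015     # g/mol
M_CH2O <- 30.03     # g/mol
P_ATM <- 101325     # Pa

#' Convert global radiation to PAR photon flux
#'
#' @param global_radiation shortwave irradiance, W/m2
#' @return PAR, umol/m2/s
#' @export
par_from_global <- function(global_radiation) {
  PAR_FRACTION * PAR_UMOL_PER_J * global_radiation
}

#' Saturation vapour pressure of water
#'
#' Magnus form, valid over the horticultural temperature range.
#'
#' @param temp_c air temperature, degC
#' @return saturation vapour pressure, Pa
#' @export
saturation_vapour_pressure <- function(temp_c) {
  610.78 * exp(17.27 * temp_c / (temp_c + 237.3))
}

#' Saturation vapour concentration of air
#'
#' @param temp_c air temperature, degC
#' @return saturated absolute humidity, g/m3
#' @export
saturation_vapour_concentration <- function(temp_c) {
  p <- saturation_vapour_pressure(temp_c)
  p * M_H2O / (R_GAS * (temp_c + 273.15))
}

#' Vapour concentration from relative humidity
#'
#' @param temp_c air temperature, degC
#' @param rh relative humidity, percent
#' @return absolute humidity, g/m3
#' @export
vapour_concentration <- function(temp_c, rh) {
  saturation_vapour_concentration(temp_c) * rh / 100
}

#' Humidity deficit of air
#'
#' Difference between the saturation and actual absolute humidity; the
#' humidity control variable used by the process computer.
#'
#' @param temp_c air temperature, degC
#' @param vapour_conc actual absolute humidity, g/m3
#' @return humidity deficit, g/m3 (non-negative)
#' @export
humidity_deficit <- function(temp_c, vapour_conc) {
  pmax(0, saturation_vapour_concentration(temp_c) - vapour_conc)
}

#' Convert a CO2 mole fraction to a mass concentration
#'
#' Uses the ideal gas law at standard pressure with temperature-dependent
#' molar air density.
#'
#' @param ppm CO2 mole fraction, ppm
#' @param temp_c air temperature, degC
#' @return CO2 mass concentration, g/m3
#' @export
co2_ppm_to_g_m3 <- function(ppm, temp_c = 20) {
  n_air <- P_ATM / (R_GAS * (temp_c + 273.15))  # mol air / m3
  ppm * 1e-6 * n_air * M_CO2
}

#' @rdname co2_ppm_to_g_m3
#' @param g_m3 CO2 mass concentration, g/m3
#' @export
co2_g_m3_to_ppm <- function(g_m3, temp_c = 20) {
  n_air <- P_ATM / (R_GAS * (temp_c + 273.15))
  g_m3 / (1e-6 * n_air * M_CO2)
}

#' Convert kWh to MJ
#'
#' The energy-use-efficiency factor can be stated either in kWh or MJ per kg
#' of fruit; reports carry kWh/kg and this helper converts when MJ/kg is
#' wanted.
#'
#' @param kwh energy, kWh
#' @return energy, MJ
#' @export
kwh_to_mj <- function(kwh) 3.6 * kwh
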