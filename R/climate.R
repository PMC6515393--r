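#' Lumped greenhouse climate simulation
#'
#' A single-air-node greenhouse model advancing inside air temperature,
#' vapour and CO2 concentrations one 5-minute step, given outside weather,
#' the current setpoint vector and the actuator capacities of the
#' compartment. All resource flows are metered. The model is a documented
#' simplification with the same inputs/outputs and limitation behaviour as
#' the process-model class it emulates: actuator caps are always honoured,
#' so e.g. a CO2 setpoint of 800 ppm is not met when the vents are wide open.
#'
#' Integration is explicit Euler at the 5-minute exchange interval with a
#' stability guard: when the fastest balance time constant falls below twice
#' the step (typically the vapour balance with vents wide open), the step is
#' subdivided.
#'
#' @name climate
NULL

#' Actuator capacities of the greenhouse compartment
#'
#' Defaults are the compartment capacities of the benchmark greenhouse:
#' rail/crop pipe peak heating 180 and 30 W/m2, ventilation area ratio
#' 0.3 m2 opening per m2 floor, HPS lighting 187 umol/m2/s, fogging
#' 330 g/m2/h, CO2 supply 15 g/m2/h.
#'
#' @param rail_pipe_peak,crop_pipe_peak peak pipe heating, W/m2
#' @param vent_area_ratio vent opening area per floor area, m2/m2
#' @param lamp_ppfd lamp photon flux at crop level when on, umol/m2/s
#' @param fog_capacity fogging capacity, g/m2/h
#' @param co2_capacity CO2 supply capacity, g/m2/h
#' @return an `actuator_limits` list
#' @export
actuator_limits <- function(rail_pipe_peak = 180, crop_pipe_peak = 30,
                            vent_area_ratio = 0.3, lamp_ppfd = 187,
                            fog_capacity = 330, co2_capacity = 15) {
  vals <- c(rail_pipe_peak, crop_pipe_peak, vent_area_ratio, lamp_ppfd,
            fog_capacity, co2_capacity)
  if (any(vals <= 0)) stop("actuator capacities must be strictly positive")
  structure(list(rail_pipe_peak = rail_pipe_peak,
                 crop_pipe_peak = crop_pipe_peak,
                 vent_area_ratio = vent_area_ratio, lamp_ppfd = lamp_ppfd,
                 fog_capacity = fog_capacity, co2_capacity = co2_capacity),
            class = "actuator_limits")
}

#' Climate model coefficients
#'
#' @param air_height effective lumped air volume per floor area, m
#' @param thermal_mass_factor multiplier on the air heat capacity accounting
#'   for crop, soil and construction buffering
#' @param cover_tau cover light transmissivity to crop level
#' @param screen_light_trans energy screen light transmission when closed
#' @param screen_loss_factor factor on the cover loss coefficient with the
#'   energy screen closed (insulation halves the loss)
#' @param blackout_light_trans blackout screen light transmission when closed
#' @param u_cover cover heat loss coefficient, W/m2/K
#' @param kp_heat proportional heating gain, W/m2/K
#' @param kp_vent proportional venting gain, percent opening per K
#' @param vent_hd_open maximum extra vent opening for dehumidification,
#'   percent
#' @param leakage infiltration air exchange with vents shut, m3/m2/s
#' @param c_wind,c_temp wind- and buoyancy-driven vent flow coefficients
#' @param lamp_efficacy HPS efficacy, umol/J (sets electric power from PPFD)
#' @param solar_heat_fraction fraction of transmitted shortwave appearing as
#'   sensible heat on the air node
#' @param transp_rad,transp_hd transpiration coefficients: g/m2/h per W/m2
#'   absorbed shortwave and per g/m3 humidity deficit
#' @param k_ext canopy extinction coefficient (shared with the crop model)
#' @param fog_kp fogging gain, g/m2/h per g/m3 of deficit excess
#' @param outside_co2 outside CO2 concentration, ppm
#' @param ua_rail,ua_crop pipe-to-air heat transfer coefficients, W/m2/K
#'   (diagnostic pipe temperatures)
#' @return a `climate_params` list
#' @export
climate_params <- function(air_height = 5, thermal_mass_factor = 8,
                           cover_tau = 0.7, screen_light_trans = 0.75,
                           screen_loss_factor = 0.5,
                           blackout_light_trans = 0.01,
                           u_cover = 4.5, kp_heat = 25, kp_vent = 15,
                           vent_hd_open = 6, leakage = 1e-4,
                           c_wind = 0.06, c_temp = 0.03,
                           lamp_efficacy = 1.8, solar_heat_fraction = 0.75,
                           transp_rad = 0.55, transp_hd = 12, k_ext = 0.8,
                           fog_kp = 150, outside_co2 = 400,
                           ua_rail = 2.0, ua_crop = 0.8) {
  as.list(environment())
}

#' Initial greenhouse state
#'
#' @param air_temp starting air temperature, degC
#' @param rh starting relative humidity, percent
#' @param co2_ppm starting CO2 concentration, ppm
#' @return a `greenhouse_state` list with zeroed resource meters
#' @export
initial_greenhouse_state <- function(air_temp = 20, rh = 80, co2_ppm = 400) {
  structure(list(air_temp = air_temp,
                 vapour_conc = vapour_concentration(air_temp, rh),
                 co2_ppm = co2_ppm,
                 rail_pipe_temp = air_temp, crop_pipe_temp = air_temp,
                 energy_screen_pos = 0, blackout_screen_pos = 0,
                 lamp_on = FALSE,
                 cum_heat = 0, cum_electricity = 0, cum_co2 = 0,
                 cum_water = 0),
            class = "greenhouse_state")
}

#' Ventilation air exchange
#'
#' Documented vent-flux relation: exchange =
#' `3600 * (leakage + (opening/100) * vent_area_ratio *
#'  (c_wind * wind + c_temp * sqrt(|dT|)))` m3/m2/h.
#' Monotone non-decreasing in opening, wind speed and |inside - outside|
#' temperature difference; equals the leakage floor at zero opening.
#'
#' @param vent_opening opening, percent of full
#' @param wind_speed outside wind, m/s (>= 0)
#' @param inside_temp,outside_temp air temperatures, degC
#' @param limits an [actuator_limits()]
#' @param params a [climate_params()] (supplies leakage and flow
#'   coefficients)
#' @return air exchange, m3/m2/h
#' @export
ventilation_exchange <- function(vent_opening, wind_speed, inside_temp,
                                 outside_temp, limits = actuator_limits(),
                                 params = climate_params()) {
  if (vent_opening < 0 || vent_opening > 100)
    stop("vent opening must be in [0, 100]")
  if (wind_speed < 0) stop("wind speed must be non-negative")
  3600 * (params$leakage + (vent_opening / 100) * limits$vent_area_ratio *
            (params$c_wind * wind_speed +
               params$c_temp * sqrt(abs(inside_temp - outside_temp))))
}

#' One step of the CO2 mass balance
#'
#' Explicit mass-balance update of the lumped CO2 store over `dt` seconds.
#' Conversion between ppm and g/m3 uses the ideal gas law at standard
#' pressure and the fixed air height.
#'
#' @param co2_ppm current concentration, ppm
#' @param injection dosing rate, g/m2/h
#' @param assimilation_sink canopy CO2 uptake, g CO2/m2/h
#' @param vent_exchange air exchange, m3/m2/h
#' @param outside_co2 outside concentration, ppm
#' @param dt step, s
#' @param air_height lumped air height, m
#' @param temp_c air temperature for the gas conversion, degC
#' @return list: `co2_ppm` (new concentration), and the step masses (g/m2)
#'   `injected`, `vented`, `assimilated` for closure bookkeeping. A
#'   concentration driven below 150 ppm clamps there (`clamped = TRUE`),
#'   with the clamp absorbed into the assimilated term so mass closure is
#'   preserved.
#' @export
co2_balance_step <- function(co2_ppm, injection, assimilation_sink,
                             vent_exchange, outside_co2 = 400, dt = 300,
                             air_height = 5, temp_c = 20) {
  stopifnot(is.finite(co2_ppm), is.finite(injection),
            is.finite(assimilation_sink), is.finite(vent_exchange))
  conc <- co2_ppm_to_g_m3(co2_ppm, temp_c)        # g/m3
  c_out <- co2_ppm_to_g_m3(outside_co2, temp_c)
  inj <- injection / 3600 * dt                     # g/m2 over step
  vented <- vent_exchange / 3600 * dt * (conc - c_out)
  assim <- assimilation_sink / 3600 * dt
  new_conc <- conc + (inj - vented - assim) / air_height
  clamped <- FALSE
  floor_conc <- co2_ppm_to_g_m3(150, temp_c)
  if (new_conc < floor_conc) {
    # absorb the deficit into the assimilation term (the canopy cannot draw
    # the store below the floor)
    assim <- assim - (floor_conc - new_conc) * air_height
    new_conc <- floor_conc
    clamped <- TRUE
  }
  list(co2_ppm = co2_g_m3_to_ppm(new_conc, temp_c),
       injected = inj, vented = vented, assimilated = assim,
       clamped = clamped)
}

#' Canopy transpiration rate
#'
#' Simplified Penman-Monteith style relation: transpiration scales with the
#' shortwave load absorbed by the canopy and with the air humidity deficit,
#' saturating with leaf area through Beer-law interception.
#'
#' @param shortwave_at_crop shortwave irradiance at crop level, W/m2
#' @param hd air humidity deficit, g/m3
#' @param lai leaf area index, m2/m2
#' @param params a [climate_params()]
#' @return transpiration, g water/m2/h
#' @export
transpiration_rate <- function(shortwave_at_crop, hd, lai,
                               params = climate_params()) {
  f <- 1 - exp(-params$k_ext * lai)
  f * (params$transp_rad * shortwave_at_crop + params$transp_hd * hd)
}

#' Advance the greenhouse climate one control interval
#'
#' Applies the setpoint vector with proportional controllers, honours every
#' actuator cap, advances the air energy, vapour and CO2 balances by
#' explicit Euler (sub-stepping under the stability guard), and advances the
#' resource meters: `cum_heat` by exactly `pipe_heat * dt`, electricity by
#' lamp power times on-time, `cum_co2` by the injected mass.
#'
#' @param state a `greenhouse_state`
#' @param weather_record one-row outside weather (global_radiation, par,
#'   air_temp, rel_humidity, wind_speed)
#' @param setpoints named setpoint vector from [resolve_setpoints()]
#' @param limits an [actuator_limits()]
#' @param dt control interval, s (> 0)
#' @param lai current crop leaf area index (drives transpiration and the
#'   CO2 assimilation sink)
#' @param params a [climate_params()]
#' @param assimilation_sink canopy CO2 uptake to impose on the CO2 balance,
#'   g CO2/m2/h; `NULL` computes it from the current climate and `lai` via
#'   [hourly_canopy_photosynthesis()]
#' @return list with `state` (advanced copy) and `fluxes`: solar_gain,
#'   lamp_heat, pipe_heat (+ rail/crop split), vent_loss, cover_loss,
#'   fog_latent (W/m2), vent_air_exchange (m3/m2/h), co2_injection (g/m2/h),
#'   transpiration (g/m2/h), par_above (umol/m2/s), plus step masses
#'   `co2_injected_g`, `co2_vented_g`, `co2_assimilated_g`, `co2_storage_g`
#'   (all g/m2) for closure checks
#' @export
step_climate <- function(state, weather_record, setpoints,
                         limits = actuator_limits(), dt = 300, lai = 3,
                         params = climate_params(),
                         assimilation_sink = NULL) {
  if (dt <= 0) stop("dt must be positive")
  if (!all(is.finite(c(state$air_temp, state$vapour_conc, state$co2_ppm))))
    stop("non-finite greenhouse state on entry")
  sp <- setpoints
  p <- params
  t_out <- weather_record$air_temp
  wind <- weather_record$wind_speed
  rad_out <- weather_record$global_radiation
  vap_out <- vapour_concentration(t_out, weather_record$rel_humidity)

  # screens track their position setpoints directly
  es <- sp[["energy_screen_pos"]] / 100
  bs <- sp[["blackout_screen_pos"]] / 100
  tau_light <- p$cover_tau *
    (1 - es * (1 - p$screen_light_trans)) *
    (1 - bs * (1 - p$blackout_light_trans))
  u_loss <- p$u_cover * (1 - es * (1 - p$screen_loss_factor)) *
    (1 - bs * 0.3)

  lamp_on <- sp[["lighting"]] >= 100
  lamp_power <- if (lamp_on) limits$lamp_ppfd / p$lamp_efficacy else 0
  par_above <- weather_record$par * tau_light +
    if (lamp_on) limits$lamp_ppfd else 0
  sw_at_crop <- rad_out * tau_light + lamp_power * 0.8

  t_air <- state$air_temp
  hd <- humidity_deficit(t_air, state$vapour_conc)

  # heating: proportional demand above the setpoint shortfall, floored by
  # the minimum-pipe setpoints, capped at the pipe peaks
  err_heat <- sp[["heating_temp"]] - t_air
  demand <- if (err_heat > 0) p$kp_heat * err_heat else 0
  rail_floor <- min(limits$rail_pipe_peak,
                    max(0, p$ua_rail * (sp[["min_rail_pipe_temp"]] - t_air)))
  crop_floor <- min(limits$crop_pipe_peak,
                    max(0, p$ua_crop * (sp[["min_crop_pipe_temp"]] - t_air)))
  rail_heat <- max(rail_floor, min(limits$rail_pipe_peak, demand))
  crop_heat <- max(crop_floor,
                   min(limits$crop_pipe_peak,
                       demand - min(limits$rail_pipe_peak, demand)))
  pipe_heat <- rail_heat + crop_heat

  # ventilation: proportional above the ventilation temperature, plus a
  # dehumidification term when the deficit is below setpoint
  vent_t <- p$kp_vent * max(0, t_air - sp[["ventilation_temp"]])
  vent_h <- if (hd < sp[["humidity_deficit_sp"]])
    p$vent_hd_open * (sp[["humidity_deficit_sp"]] - hd) /
      max(sp[["humidity_deficit_sp"]], 0.1) else 0
  opening <- min(100, max(sp[["min_vent_opening"]], vent_t + vent_h))
  phi <- ventilation_exchange(opening, wind, t_air, t_out, limits, p) / 3600

  # fogging adds vapour (and latent cooling) when the air is too dry
  fog <- min(limits$fog_capacity,
             p$fog_kp * max(0, hd - sp[["humidity_deficit_sp"]]))

  transp <- transpiration_rate(sw_at_crop, hd, lai, p)

  # CO2 dosing: the dosing computer supplies what the balance needs to hold
  # the setpoint over the coming interval (deficit refill plus vent and
  # canopy losses), capped at supply capacity
  if (is.null(assimilation_sink)) {
    a_ch2o <- hourly_canopy_photosynthesis(par_above, state$co2_ppm, t_air,
                                           100 * state$vapour_conc /
                                             saturation_vapour_concentration(t_air),
                                           lai)
    assimilation_sink <- a_ch2o * M_CO2 / M_CH2O
  }
  conc_now <- co2_ppm_to_g_m3(state$co2_ppm, t_air)
  conc_sp <- co2_ppm_to_g_m3(sp[["co2_sp"]], t_air)
  need <- (conc_sp - conc_now) * p$air_height * 3600 / dt +
    phi * 3600 * (conc_now - co2_ppm_to_g_m3(p$outside_co2, t_air)) +
    assimilation_sink
  injection <- min(limits$co2_capacity, max(0, need))

  # --- balance integration with stability guard ---
  c_eff <- RHO_AIR * CP_AIR * p$air_height * p$thermal_mass_factor
  u_tot <- u_loss + RHO_AIR * CP_AIR * phi
  tau_t <- c_eff / max(u_tot, 1e-9)
  tau_gas <- p$air_height / max(phi, 1e-9)
  tau_min <- min(tau_t, tau_gas)
  n_sub <- if (tau_min < 2 * dt) min(120L, as.integer(ceiling(2 * dt / tau_min))) else 1L
  h <- dt / n_sub

  solar_gain <- p$solar_heat_fraction * rad_out * tau_light
  fog_latent <- fog * LATENT_HEAT_VAPOUR / 3600
  transp_latent <- transp * LATENT_HEAT_VAPOUR / 3600

  vap <- state$vapour_conc
  conc <- co2_ppm_to_g_m3(state$co2_ppm, t_air)
  c_out_co2 <- co2_ppm_to_g_m3(p$outside_co2, t_air)
  co2_store0 <- conc * p$air_height
  inj_g <- vented_g <- assim_g <- 0
  cover_loss_acc <- vent_loss_acc <- 0
  temp0 <- t_air

  for (s in seq_len(n_sub)) {
    cover_loss <- u_loss * (t_air - t_out)
    vent_loss <- RHO_AIR * CP_AIR * phi * (t_air - t_out)
    q_net <- solar_gain + lamp_power + pipe_heat - cover_loss - vent_loss -
      fog_latent - transp_latent
    t_air <- t_air + q_net * h / c_eff
    cover_loss_acc <- cover_loss_acc + cover_loss / n_sub
    vent_loss_acc <- vent_loss_acc + vent_loss / n_sub

    vap <- vap + ((transp + fog) / 3600 - phi * (vap - vap_out)) * h /
      p$air_height
    vap <- min(vap, saturation_vapour_concentration(t_air))  # condensation

    dinj <- injection / 3600 * h
    dvent <- phi * (conc - c_out_co2) * h
    dassim <- assimilation_sink / 3600 * h
    conc <- conc + (dinj - dvent - dassim) / p$air_height
    floor_conc <- co2_ppm_to_g_m3(150, temp0)
    if (conc < floor_conc) {
      dassim <- dassim - (floor_conc - conc) * p$air_height
      conc <- floor_conc
    }
    inj_g <- inj_g + dinj; vented_g <- vented_g + dvent
    assim_g <- assim_g + dassim
  }

  if (!all(is.finite(c(t_air, vap, conc))))
    stop("non-finite climate balance (diagnostic: T=", t_air,
         " vap=", vap, " co2=", conc, ")")

  new <- state
  new$air_temp <- t_air
  new$vapour_conc <- vap
  new$co2_ppm <- co2_g_m3_to_ppm(conc, temp0)
  new$rail_pipe_temp <- t_air + rail_heat / p$ua_rail
  new$crop_pipe_temp <- t_air + crop_heat / p$ua_crop
  new$energy_screen_pos <- sp[["energy_screen_pos"]]
  new$blackout_screen_pos <- sp[["blackout_screen_pos"]]
  new$lamp_on <- lamp_on
  new$cum_heat <- state$cum_heat + pipe_heat * dt / 3.6e6
  new$cum_electricity <- state$cum_electricity + lamp_power * dt / 3.6e6
  new$cum_co2 <- state$cum_co2 + inj_g / 1000

  fluxes <- list(solar_gain = solar_gain, lamp_heat = lamp_power,
                 pipe_heat = pipe_heat, rail_heat = rail_heat,
                 crop_heat = crop_heat,
                 vent_loss = vent_loss_acc, cover_loss = cover_loss_acc,
                 fog_latent = fog_latent,
                 vent_air_exchange = phi * 3600, vent_opening = opening,
                 co2_injection = injection, transpiration = transp,
                 par_above = par_above,
                 assimilation_sink = assimilation_sink,
                 co2_injected_g = inj_g, co2_vented_g = vented_g,
                 co2_assimilated_g = assim_g,
                 co2_storage_g = conc * p$air_height - co2_store0,
                 co2_store_mass_g = co2_store0,
                 n_sub = n_sub)
  list(state = new, fluxes = fluxes)
}
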