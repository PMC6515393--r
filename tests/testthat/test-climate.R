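test_that("lamps add exactly the lamp PPFD to PAR above the crop", {
  wrec <- test_weather_record(global_radiation = 200, air_temp = 12)
  st <- initial_greenhouse_state()
  on <- step_climate(st, wrec, test_setpoints(lighting = 100), lai = 3)
  off <- step_climate(st, wrec, test_setpoints(lighting = 0), lai = 3)
  expect_equal(on$fluxes$par_above - off$fluxes$par_above, 187)
  # lamp electricity metered as power x on-time
  expect_equal(on$state$cum_electricity,
               (187 / climate_params()$lamp_efficacy) * 300 / 3.6e6)
  expect_equal(off$state$cum_electricity, 0)
})

test_that("CO2 dosing is capped at supply capacity with vents shut", {
  wrec <- test_weather_record(air_temp = 15)
  st <- initial_greenhouse_state(co2_ppm = 400)
  r <- step_climate(st, wrec, test_setpoints(co2_sp = 1000, lighting = 0),
                    lai = 3)
  expect_equal(r$fluxes$co2_injection, 15)
})

test_that("heating respects pipe peaks and meters energy exactly", {
  wrec <- test_weather_record(air_temp = -5, wind_speed = 8)
  st <- initial_greenhouse_state(air_temp = 5)
  r <- step_climate(st, wrec, test_setpoints(heating_temp = 26,
                                             ventilation_temp = 28), lai = 3)
  expect_lte(r$fluxes$pipe_heat, 180 + 30)
  expect_lte(r$fluxes$rail_heat, 180)
  expect_lte(r$fluxes$crop_heat, 30)
  expect_equal(r$state$cum_heat, r$fluxes$pipe_heat * 300 / 3.6e6)
})

test_that("a minimum rail-pipe setpoint forces base heat while venting", {
  # warm house, vents open, no heating demand: the pipe minimum still burns
  wrec <- test_weather_record(air_temp = 18)
  st <- initial_greenhouse_state(air_temp = 24)
  sp_off <- test_setpoints(heating_temp = 19, ventilation_temp = 20)
  sp_min <- test_setpoints(heating_temp = 19, ventilation_temp = 20,
                           min_rail_pipe_temp = 40)
  r_off <- step_climate(st, wrec, sp_off, lai = 3)
  r_min <- step_climate(st, wrec, sp_min, lai = 3)
  expect_equal(r_off$fluxes$pipe_heat, 0)
  expect_gt(r_min$fluxes$pipe_heat, 0)
  expect_gt(r_min$fluxes$vent_opening, 0)
})

test_that("without inputs the air temperature converges to outside", {
  wrec <- test_weather_record(air_temp = 10, wind_speed = 4)
  # heating and fogging disabled, vents wide open
  sp <- test_setpoints(heating_temp = -30, ventilation_temp = -20,
                       min_vent_opening = 100, humidity_deficit_sp = 99,
                       co2_sp = 400)
  st <- initial_greenhouse_state(air_temp = 25, rh = 60)
  for (i in 1:300) st <- step_climate(st, wrec, sp, lai = 0)$state
  expect_equal(st$air_temp, 10, tolerance = 0.01)
})

test_that("ventilation exchange follows the documented formula and its
           monotonicities", {
  lim <- actuator_limits()
  p <- climate_params()
  expect_equal(ventilation_exchange(0, 5, 20, 10, lim,
                                    climate_params(leakage = 0)), 0)
  # independent re-evaluation of the documented relation
  ex <- ventilation_exchange(50, 4, 20, 15, lim, p)
  oracle <- 3600 * (p$leakage + 0.5 * lim$vent_area_ratio *
                      (p$c_wind * 4 + p$c_temp * sqrt(5)))
  expect_equal(ex, oracle)
  expect_gt(ventilation_exchange(50, 8, 20, 15, lim, p), ex)
  expect_gt(ventilation_exchange(80, 4, 20, 15, lim, p), ex)
  expect_gt(ventilation_exchange(50, 4, 25, 15, lim, p), ex)
  expect_error(ventilation_exchange(50, -1, 20, 15, lim, p), "non-negative")
  expect_error(ventilation_exchange(130, 3, 20, 15, lim, p), "\\[0, 100\\]")
})

test_that("the CO2 balance relaxes to outside, rises linearly when closed,
           and closes its mass budget", {
  # exchange with outside at 400 ppm pulls the store toward 400
  c <- 800
  for (i in 1:500)
    c <- co2_balance_step(c, 0, 0, vent_exchange = 20, outside_co2 = 400,
                          dt = 300)$co2_ppm
  expect_equal(c, 400, tolerance = 0.01)

  # closed greenhouse, constant injection, no sink: linear rise at
  # injection/(height x conversion)
  r1 <- co2_balance_step(400, injection = 10, assimilation_sink = 0,
                         vent_exchange = 0, dt = 3600, air_height = 5,
                         temp_c = 20)
  rise_gm3 <- 10 / 5                        # g/m2/h over 5 m for one hour
  expected <- co2_g_m3_to_ppm(co2_ppm_to_g_m3(400, 20) + rise_gm3, 20)
  expect_equal(r1$co2_ppm, expected, tolerance = 1e-12)

  # mass closure including the clamp pathway
  r2 <- co2_balance_step(160, injection = 0, assimilation_sink = 50,
                         vent_exchange = 0, dt = 3600)
  store <- (co2_ppm_to_g_m3(r2$co2_ppm) - co2_ppm_to_g_m3(160)) * 5
  expect_equal(store, r2$injected - r2$vented - r2$assimilated,
               tolerance = 1e-12)
  expect_true(r2$clamped)
  expect_equal(r2$co2_ppm, 150)
})

test_that("a closed energy screen reduces heat loss and heating energy", {
  wrec <- test_weather_record(air_temp = 0, wind_speed = 4)
  st <- initial_greenhouse_state(air_temp = 20)
  open <- step_climate(st, wrec, test_setpoints(energy_screen_pos = 0),
                       lai = 3)
  closed <- step_climate(st, wrec, test_setpoints(energy_screen_pos = 100),
                         lai = 3)
  expect_lt(closed$fluxes$cover_loss, open$fluxes$cover_loss)

  # at the controlled steady state the pipes replace the losses, so the
  # screened house heats less, other things equal
  run_to_ss <- function(screen) {
    st <- initial_greenhouse_state(air_temp = 18)
    sp <- test_setpoints(heating_temp = 20, ventilation_temp = 24,
                         energy_screen_pos = screen)
    for (i in 1:200) r <- { out <- step_climate(st, wrec, sp, lai = 3)
                            st <- out$state; out }
    r$fluxes$pipe_heat
  }
  expect_lt(run_to_ss(100), run_to_ss(0))
})

test_that("climate stepping rejects bad inputs", {
  wrec <- test_weather_record()
  st <- initial_greenhouse_state()
  expect_error(step_climate(st, wrec, test_setpoints(), dt = 0), "positive")
  bad <- st
  bad$air_temp <- NaN
  expect_error(step_climate(bad, wrec, test_setpoints(), lai = 2),
               "non-finite")
  expect_error(actuator_limits(co2_capacity = 0), "positive")
})
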