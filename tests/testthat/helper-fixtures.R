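# Shared fixtures. Season runs are the expensive part of the suite, so they
# are memoised: each named run is computed once per test session.

.run_cache <- new.env(parent = emptyenv())

run_cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache)) {
    assign(key, force(expr), envir = .run_cache)
  }
  get(key, envir = .run_cache)
}

# a mid-length reference season (transplant to mid-October): long enough to
# carry a full harvest pipeline, short enough to keep the suite quick
short_ref_scenario <- function(end_date = "2018-10-13", seed = 11, ...) {
  scenario("reference", reference_grower_strategy(), end_date = end_date,
           weather_seed = seed, ...)
}

short_ref_run <- function() {
  run_cached("short_ref", run_scenario(short_ref_scenario()))
}

# a constant synthetic day for crop-model unit tests: `par_day` during 12
# daylight hours, constant temperature/CO2/humidity
constant_day <- function(date, par_day, temp = 21, co2 = 700, rh = 80) {
  daily_climate_aggregate(date,
                          par = c(rep(0, 6), rep(par_day, 12), rep(0, 6)),
                          temp = rep(temp, 24), co2 = rep(co2, 24),
                          rh = rep(rh, 24))
}

# run the daily crop model for n days under a constant climate
run_constant_crop <- function(n_days, par_day, temp = 21, co2 = 700,
                              plan = cropping_plan(),
                              params = crop_params(),
                              start = as.Date("2018-08-14")) {
  crop <- initial_crop_state(plan, params)
  harvests <- vector("list", n_days)
  diags <- vector("list", n_days)
  for (d in seq_len(n_days)) {
    agg <- constant_day(start + d - 1, par_day, temp, co2)
    up <- daily_crop_update(crop, agg, plan, params)
    crop <- up$crop
    harvests[[d]] <- up$harvest
    diags[[d]] <- up$diag
  }
  list(crop = crop, harvests = do.call(rbind, harvests), diags = diags)
}

# neutral setpoint vector for direct climate-step tests
test_setpoints <- function(...) {
  sp <- c(min_rail_pipe_temp = 0, min_crop_pipe_temp = 0, heating_temp = 20,
          ventilation_temp = 22, min_vent_opening = 0,
          humidity_deficit_sp = 2.5, energy_screen_pos = 0,
          blackout_screen_pos = 0, lighting = 0, co2_sp = 600,
          irrigation_interval = 60)
  over <- c(...)
  sp[names(over)] <- over
  sp
}

test_weather_record <- function(global_radiation = 0, air_temp = 10,
                                rel_humidity = 80, wind_speed = 3) {
  list(global_radiation = global_radiation,
       par = par_from_global(global_radiation), air_temp = air_temp,
       rel_humidity = rel_humidity, wind_speed = wind_speed)
}
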