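#' Strategies and setpoint resolution
#'
#' A strategy bundles the cropping choices (stem density, pruning, topping)
#' with piecewise-constant climate schedules, and resolves to the 11-element
#' setpoint vector the process computer consumes every 5 minutes: minimum
#' rail/crop pipe temperatures, heating and ventilation temperatures, minimum
#' vent opening, humidity deficit setpoint, energy and blackout screen
#' positions, lighting on/off, CO2 setpoint and irrigation interval.
#'
#' Day/night transitions are at fixed clock times (default 07:00/19:00);
#' lighting follows a clock window with a radiation-threshold override (lamps
#' only run when outside global radiation is below the threshold).
#'
#' @name strategy
NULL

SETPOINT_NAMES <- c("min_rail_pipe_temp", "min_crop_pipe_temp", "heating_temp",
                    "ventilation_temp", "min_vent_opening",
                    "humidity_deficit_sp", "energy_screen_pos",
                    "blackout_screen_pos", "lighting", "co2_sp",
                    "irrigation_interval")

#' Construct a cropping plan
#'
#' @param stem_density fruiting stems per m2 (sane band roughly 2-4)
#' @param fruit_prune_pattern repeating sequence of fruit-prune fractions
#'   applied to successive cohorts (e.g. `c(0.5, 0.67)` removes alternately
#'   50% and 67% of set fruits)
#' @param leaf_prune_fraction fraction of newly formed leaves removed
#' @param topping_date date the shoot apex is removed; no new leaves or
#'   fruit cohorts initiate afterwards
#' @param end_date last harvest date of the season
#' @param stems_per_plant stems trained per young plant (sets plant costs)
#' @return a `cropping_plan` list
#' @export
cropping_plan <- function(stem_density = 2.5,
                          fruit_prune_pattern = c(0.5, 0.5),
                          leaf_prune_fraction = 0,
                          topping_date = "2018-11-09",
                          end_date = "2018-12-07",
                          stems_per_plant = 1) {
  topping_date <- as.Date(topping_date)
  end_date <- as.Date(end_date)
  if (stem_density <= 0 || stem_density > 6)
    stop("stem_density outside the sane band (0, 6]")
  if (any(fruit_prune_pattern < 0 | fruit_prune_pattern > 1))
    stop("fruit prune fractions must be in [0, 1]")
  if (leaf_prune_fraction < 0 || leaf_prune_fraction > 1)
    stop("leaf_prune_fraction must be in [0, 1]")
  if (topping_date >= end_date) stop("topping_date must precede end_date")
  structure(list(stem_density = stem_density,
                 fruit_prune_pattern = fruit_prune_pattern,
                 leaf_prune_fraction = leaf_prune_fraction,
                 topping_date = topping_date, end_date = end_date,
                 stems_per_plant = stems_per_plant),
            class = "cropping_plan")
}

#' Construct a strategy
#'
#' @param name strategy label
#' @param cropping a [cropping_plan()]
#' @param heat_day,heat_night heating temperature setpoints, degC
#' @param vent_offset ventilation temperature = heating temperature + offset,
#'   degC (>= the controller dead-band, so vents never undercut heating)
#' @param day_start,day_end day period clock hours (decimal)
#' @param light_start,light_end lamp window clock hours (decimal)
#' @param light_threshold lamps on inside the window only while outside
#'   global radiation is below this, W/m2
#' @param co2_day,co2_night CO2 setpoints, ppm (floored at ambient 400)
#' @param co2_ramp weekly increment of the day CO2 setpoint, ppm/week
#'   (Sonoma-style rising enrichment); capped at 1000
#' @param hd_sp humidity deficit setpoint, g/m3
#' @param min_vent minimum vent opening, percent
#' @param min_rail_pipe,min_crop_pipe minimum pipe temperatures, degC
#' @param screen_close_temp energy screen closes at night below this outside
#'   temperature, degC
#' @param blackout_with_lamps close the blackout screen while lamps run at
#'   night (blocks natural light; it sits below the lamps)
#' @param irrigation_interval_day,irrigation_interval_night minutes between
#'   irrigation turns
#' @return a `strategy` list
#' @export
strategy <- function(name, cropping = cropping_plan(),
                     heat_day = 22, heat_night = 19, vent_offset = 2,
                     day_start = 7, day_end = 19,
                     light_start = 4, light_end = 18, light_threshold = 150,
                     co2_day = 600, co2_night = 400, co2_ramp = 0,
                     hd_sp = 2.5, min_vent = 0,
                     min_rail_pipe = 35, min_crop_pipe = 0,
                     screen_close_temp = 14, blackout_with_lamps = FALSE,
                     irrigation_interval_day = 40,
                     irrigation_interval_night = 180) {
  if (vent_offset < 0.5)
    stop("vent_offset below the controller dead-band (0.5 degC)")
  if (co2_day < 400 || co2_night < 400)
    stop("CO2 setpoints must be at or above the 400 ppm ambient floor")
  structure(list(name = name, cropping = cropping,
                 heat_day = heat_day, heat_night = heat_night,
                 vent_offset = vent_offset,
                 day_start = day_start, day_end = day_end,
                 light_start = light_start, light_end = light_end,
                 light_threshold = light_threshold,
                 co2_day = co2_day, co2_night = co2_night, co2_ramp = co2_ramp,
                 hd_sp = hd_sp, min_vent = min_vent,
                 min_rail_pipe = min_rail_pipe, min_crop_pipe = min_crop_pipe,
                 screen_close_temp = screen_close_temp,
                 blackout_with_lamps = blackout_with_lamps,
                 irrigation_interval_day = irrigation_interval_day,
                 irrigation_interval_night = irrigation_interval_night),
            class = "strategy")
}

clock_hour <- function(timestamp) {
  as.numeric(strftime(timestamp, "%H", tz = "UTC")) +
    as.numeric(strftime(timestamp, "%M", tz = "UTC")) / 60
}

in_window <- function(h, start, end) {
  if (start <= end) h >= start & h < end else h >= start | h < end
}

#' Resolve a strategy to a setpoint vector
#'
#' Pure function of (strategy, timestamp, weather record): schedule
#' boundaries use local clock time; radiation-conditioned rules read only
#' the supplied weather record.
#'
#' @param strat a [strategy()]
#' @param timestamp POSIXct within the season
#' @param weather_record one-row weather data (needs `global_radiation`,
#'   `air_temp`)
#' @param season_start season start date, used for the weekly CO2 ramp
#' @return named numeric vector with the 11 setpoints
#' @export
resolve_setpoints <- function(strat, timestamp, weather_record,
                              season_start = as.Date("2018-08-14")) {
  if (as.Date(timestamp) > strat$cropping$end_date)
    stop("timestamp outside the cropping season")
  sp <- resolve_core(strat, as.Date(timestamp), clock_hour(timestamp),
                     weather_record$global_radiation,
                     weather_record$air_temp, season_start)
  validate_setpoints(sp)
  sp
}

# setpoint resolution with pre-split time components; the hot path of the
# season loop
resolve_core <- function(strat, date, h, rad, t_out,
                         season_start = as.Date("2018-08-14")) {
  is_day <- in_window(h, strat$day_start, strat$day_end)

  lighting <- if (in_window(h, strat$light_start, strat$light_end) &&
                  rad < strat$light_threshold) 100 else 0

  week <- as.numeric(date - season_start) / 7
  co2_sp <- if (is_day) min(1000, strat$co2_day + strat$co2_ramp * week)
            else strat$co2_night

  night <- !is_day
  energy_screen <- if (night && t_out < strat$screen_close_temp) 100 else 0
  blackout <- if (strat$blackout_with_lamps && night && lighting == 100) 100 else 0

  sp <- c(min_rail_pipe_temp = strat$min_rail_pipe,
          min_crop_pipe_temp = strat$min_crop_pipe,
          heating_temp = if (is_day) strat$heat_day else strat$heat_night,
          ventilation_temp = (if (is_day) strat$heat_day else strat$heat_night) +
            strat$vent_offset,
          min_vent_opening = strat$min_vent,
          humidity_deficit_sp = strat$hd_sp,
          energy_screen_pos = energy_screen,
          blackout_screen_pos = blackout,
          lighting = lighting,
          co2_sp = co2_sp,
          irrigation_interval = if (is_day) strat$irrigation_interval_day
                                else strat$irrigation_interval_night)
  sp
}

#' Validate a setpoint vector
#'
#' Checks the setpoint invariants: percentages in `[0, 100]`, lighting in
#' `{0, 100}`, ventilation temperature at or above heating temperature minus
#' the dead-band, CO2 setpoint at or above the ambient floor.
#'
#' @param sp named numeric vector as produced by [resolve_setpoints()]
#' @param dead_band heating/ventilation dead-band, degC
#' @return `sp` invisibly; errors if invalid
#' @export
validate_setpoints <- function(sp, dead_band = 0.5) {
  stopifnot(identical(sort(names(sp)), sort(SETPOINT_NAMES)))
  pct <- c("min_vent_opening", "energy_screen_pos", "blackout_screen_pos")
  if (any(sp[pct] < 0 | sp[pct] > 100)) stop("percentage setpoint outside [0, 100]")
  if (!sp[["lighting"]] %in% c(0, 100)) stop("lighting must be 0 or 100")
  if (sp[["ventilation_temp"]] < sp[["heating_temp"]] - dead_band)
    stop("ventilation temperature undercuts heating temperature")
  if (sp[["co2_sp"]] < 400) stop("CO2 setpoint below ambient floor")
  if (sp[["irrigation_interval"]] <= 0) stop("irrigation interval must be positive")
  invisible(sp)
}

#' The manual-grower baseline strategy
#'
#' A fully specified baseline profile: 2.5 stems/m2, constant 50% fruit
#' prune, no leaf pruning, topping on 9 November, moderate lighting and CO2,
#' 19/22 degC night/day heating. The schedule details beyond the published
#' scalars (stem density, topping date) are stylized.
#'
#' @return a `strategy`
#' @export
reference_grower_strategy <- function() {
  strategy("Reference",
           cropping = cropping_plan(stem_density = 2.5,
                                    fruit_prune_pattern = c(0.5, 0.5),
                                    leaf_prune_fraction = 0,
                                    topping_date = "2018-11-09",
                                    stems_per_plant = 1),
           heat_day = 22, heat_night = 19,
           light_start = 6, light_end = 18, light_threshold = 120,
           co2_day = 600, co2_night = 400,
           hd_sp = 2.5)
}

#' Stylized team strategy profiles
#'
#' Five named profiles carrying the published stem densities and the
#' qualitatively documented light/CO2/temperature characters: Sonoma (high
#' light, continuously rising CO2), AiCU (cool, low light, highest fruit
#' density), deep_greens (very warm, heavy lamp use behind a blackout
#' screen), iGrow (moderate everything), The Croperators (warm days, late
#' CO2, alternating heavy fruit prune). These are stylized reconstructions
#' for counterfactual demonstrations, not the teams' actual trajectories;
#' only stem densities and the topping-date band are anchored to published
#' values.
#'
#' @return named list of `strategy` objects
#' @export
team_profile_strategies <- function() {
  list(
    Sonoma = strategy("Sonoma",
      cropping = cropping_plan(stem_density = 3.3,
                               fruit_prune_pattern = c(0.5, 0.5),
                               topping_date = "2018-11-26",
                               stems_per_plant = 1.75),
      heat_day = 22.5, heat_night = 19.5,
      light_start = 0, light_end = 18, light_threshold = 250,
      co2_day = 600, co2_ramp = 22, co2_night = 450),
    iGrow = strategy("iGrow",
      cropping = cropping_plan(stem_density = 2.6,
                               fruit_prune_pattern = c(0.5, 0.5),
                               topping_date = "2018-11-22",
                               stems_per_plant = 1.3),
      heat_day = 22, heat_night = 19,
      light_start = 4, light_end = 18, light_threshold = 150,
      co2_day = 650, co2_night = 400),
    deep_greens = strategy("deep_greens",
      cropping = cropping_plan(stem_density = 2.6,
                               fruit_prune_pattern = c(0.5, 0.5),
                               topping_date = "2018-11-21",
                               stems_per_plant = 1.3),
      heat_day = 25, heat_night = 22,
      light_start = 0, light_end = 20, light_threshold = 300,
      co2_day = 800, co2_night = 500,
      blackout_with_lamps = TRUE),
    The_Croperators = strategy("The Croperators",
      cropping = cropping_plan(stem_density = 3.2,
                               fruit_prune_pattern = c(0.5, 0.67),
                               topping_date = "2018-11-19",
                               stems_per_plant = 1.6),
      heat_day = 25, heat_night = 19,
      light_start = 2, light_end = 18, light_threshold = 200,
      co2_day = 500, co2_night = 400),
    AiCU = strategy("AiCU",
      cropping = cropping_plan(stem_density = 3.6,
                               fruit_prune_pattern = c(0.33, 0.33),
                               topping_date = "2018-11-28",
                               stems_per_plant = 1.8),
      heat_day = 20, heat_night = 18.5,
      light_start = 6, light_end = 16, light_threshold = 100,
      co2_day = 700, co2_night = 400)
  )
}

#' Read and write strategy YAML files
#'
#' Strategies serialize to a flat YAML document; dates as ISO strings.
#' Round-trips exactly through [read_strategy_yaml()].
#'
#' @param strat a `strategy`
#' @param path file path
#' @export
write_strategy_yaml <- function(strat, path) {
  x <- unclass(strat)
  x$cropping <- unclass(x$cropping)
  x$cropping$topping_date <- format(x$cropping$topping_date)
  x$cropping$end_date <- format(x$cropping$end_date)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_strategy_yaml
#' @export
read_strategy_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  cp <- do.call(cropping_plan, x$cropping)
  x$cropping <- NULL
  do.call(strategy, c(list(cropping = cp), x))
}
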