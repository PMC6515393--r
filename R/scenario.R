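#' Full-season scenarios and the strategy-swap analysis
#'
#' A scenario bundles a strategy, an outside weather series and the full
#' configuration (actuator limits, climate and crop parameters, prices), so
#' two runs of the same scenario give identical results. `run_scenario`
#' drives the 5-minute climate loop through the season, feeds hourly
#' aggregates to the daily crop model, books irrigation water, and closes
#' with the economic and sustainability reports. `swap_strategy` and
#' `swap_matrix` implement the counterfactual analysis: exchange exactly one
#' strategy facet (cropping, lighting or CO2) between scenarios and
#' re-simulate.
#'
#' @name scenario
NULL

#' Construct a scenario
#'
#' @param name scenario label
#' @param strat a [strategy()]
#' @param weather a `weather_series`, or `NULL` to generate one from
#'   `weather_seed` over the season
#' @param start_date season start (transplant date)
#' @param end_date last day; defaults to the strategy's cropping end date
#' @param weather_seed seed for the generated weather
#' @param latitude site latitude, degrees north
#' @param limits an [actuator_limits()]
#' @param cparams a [climate_params()]
#' @param kparams a [crop_params()]
#' @param prices a [weekly_price_series()] (`NULL`: default ramp sized to
#'   the season)
#' @param uprices a [unit_prices()]
#' @param shot_size irrigation shot, L/m2 per turn
#' @param deficit_hook apply the crop stress penalty on irrigation-deficit
#'   days (off by default; the validation analysis switches it on)
#' @param blackout_days optional Date vector during which irrigation events
#'   are suppressed (equipment-failure counterfactual)
#' @return a `scenario` list
#' @export
scenario <- function(name, strat, weather = NULL,
                     start_date = "2018-08-14", end_date = NULL,
                     weather_seed = 1, latitude = 52,
                     limits = actuator_limits(), cparams = climate_params(),
                     kparams = crop_params(), prices = NULL,
                     uprices = unit_prices(), shot_size = 0.1,
                     deficit_hook = FALSE, blackout_days = NULL) {
  start_date <- as.Date(start_date)
  end_date <- as.Date(if (is.null(end_date)) strat$cropping$end_date
                      else end_date)
  if (is.null(weather))
    weather <- generate_weather(start_date, end_date, latitude, weather_seed)
  n_weeks <- as.integer(ceiling(as.numeric(end_date - start_date) / 7)) + 1L
  if (is.null(prices)) prices <- weekly_price_series(n_weeks)
  structure(list(name = name, strategy = strat, weather = weather,
                 start_date = start_date, end_date = end_date,
                 weather_seed = weather_seed, latitude = latitude,
                 limits = limits, cparams = cparams, kparams = kparams,
                 prices = prices, uprices = uprices, shot_size = shot_size,
                 deficit_hook = deficit_hook, blackout_days = blackout_days),
            class = "scenario")
}

#' Run a scenario over the full season
#'
#' The 5-minute climate loop resolves setpoints, steps the climate balances
#' and irrigation bookkeeping, aggregates the inside climate to hourly
#' values, and at each midnight advances the crop one day, closes the water
#' ledger and logs the daily record. Deterministic: all randomness sits in
#' the scenario's weather seed.
#'
#' @param sc a [scenario()]
#' @return a `simulation_result` list: `daily` (per-day data.frame),
#'   `harvests`, `aggregates` (list of daily climate aggregates),
#'   `resources`, `income`, `ledger`, `net_profit`, `sustainability`,
#'   `yield_kg` (total fresh), `marketable_yield_kg` (A+B),
#'   `fruits_per_m2`, `yield_prior_to_topping`, `aborted_per_m2`,
#'   `flux_extremes` and `co2_closure_max_err`
#' @export
run_scenario <- function(sc) {
  wx <- sc$weather
  strat <- sc$strategy
  plan <- strat$cropping
  p <- sc$cparams
  kp <- sc$kparams
  limits <- sc$limits
  n_days <- as.integer(sc$end_date - sc$start_date)
  if (nrow(wx) < n_days * 288 + 1)
    stop("weather series shorter than the season")

  gr <- wx$global_radiation; pr <- wx$par; at <- wx$air_temp
  rh <- wx$rel_humidity; ws <- wx$wind_speed

  state <- initial_greenhouse_state(air_temp = at[1] + 2,
                                    rh = min(95, rh[1]), co2_ppm = 400)
  crop <- initial_crop_state(plan, kp)
  irr <- initial_irrigation_state(sc$shot_size)

  daily <- vector("list", n_days)
  harvests <- vector("list", n_days)
  aggregates <- vector("list", n_days)
  water <- vector("list", n_days)
  ext <- c(max_co2_inj = 0, max_fog = 0, max_pipe = 0, max_lamp_par = 0)
  co2_err <- 0
  stress_next <- 1
  total_harvest_kg <- 0

  for (d in seq_len(n_days)) {
    date <- sc$start_date + d - 1L
    hsum <- matrix(0, 4, 24)   # par, temp, co2, rh sums per hour
    trans_day <- 0
    blackout <- !is.null(sc$blackout_days) && date %in% sc$blackout_days

    for (j in seq_len(288)) {
      i <- (d - 1L) * 288L + j
      h <- (j - 1L) * 5 / 60
      wrec <- list(global_radiation = gr[i], par = pr[i], air_temp = at[i],
                   rel_humidity = rh[i], wind_speed = ws[i])
      sp <- resolve_core(strat, date, h, gr[i], at[i], sc$start_date)
      res <- step_climate(state, wrec, sp, limits, dt = 300,
                          lai = crop$lai, params = p)
      state <- res$state
      fx <- res$fluxes

      if (!blackout)
        irr <- irrigation_step(irr, sp[["irrigation_interval"]],
                               fx$transpiration, dt = 300)
      else
        irr$day_uptake_demand <- irr$day_uptake_demand +
          fx$transpiration * 300 / 3600 / 1000

      hr <- ((j - 1L) %/% 12L) + 1L
      hsum[1, hr] <- hsum[1, hr] + fx$par_above
      hsum[2, hr] <- hsum[2, hr] + state$air_temp
      hsum[3, hr] <- hsum[3, hr] + state$co2_ppm
      hsum[4, hr] <- hsum[4, hr] + 100 * state$vapour_conc /
        saturation_vapour_concentration(state$air_temp)
      trans_day <- trans_day + fx$transpiration * 300 / 3600

      if (fx$co2_injection > ext[["max_co2_inj"]])
        ext[["max_co2_inj"]] <- fx$co2_injection
      if (fx$fog_latent * 3600 / LATENT_HEAT_VAPOUR > ext[["max_fog"]])
        ext[["max_fog"]] <- fx$fog_latent * 3600 / LATENT_HEAT_VAPOUR
      if (fx$pipe_heat > ext[["max_pipe"]]) ext[["max_pipe"]] <- fx$pipe_heat
      if (state$lamp_on && fx$par_above > ext[["max_lamp_par"]])
        ext[["max_lamp_par"]] <- fx$par_above
      # closure error relative to the conserved store mass
      err <- abs(fx$co2_storage_g -
                   (fx$co2_injected_g - fx$co2_vented_g -
                      fx$co2_assimilated_g)) / fx$co2_store_mass_g
      if (err > co2_err) co2_err <- err
    }

    agg <- daily_climate_aggregate(date, hsum[1, ] / 12, hsum[2, ] / 12,
                                   hsum[3, ] / 12, hsum[4, ] / 12)
    aggregates[[d]] <- agg
    up <- daily_crop_update(crop, agg, plan, kp, stress_factor = stress_next)
    crop <- up$crop

    wd <- close_water_day(irr, date)
    irr <- wd$irr
    state$cum_water <- state$cum_water + wd$ledger$net_use
    deficit <- wd$ledger$deficit

    if (sc$deficit_hook && deficit) {
      stress_next <- 0.2
      if (nrow(crop$cohorts))
        crop$cohorts$aborted <- crop$cohorts$aborted | crop$cohorts$dev < 0.4
    } else stress_next <- 1

    hv <- up$harvest
    total_harvest_kg <- total_harvest_kg + hv$mass_a + hv$mass_b + hv$mass_c
    harvests[[d]] <- hv
    water[[d]] <- wd$ledger
    daily[[d]] <- data.frame(
      date = date, dli = agg$dli, mean_temp = agg$mean_temp,
      mean_co2 = mean(agg$co2), lai = crop$lai,
      gross = up$diag$gross, pool = up$diag$pool,
      alloc_total = up$diag$alloc_total, reserve = up$diag$reserve,
      demand = up$diag$demand, ratio = up$diag$ratio,
      aborted_today = up$diag$aborted_today,
      aborted_fruits = up$diag$aborted_fruits_today,
      starvation = up$diag$starvation,
      count_a = hv$count_a, count_b = hv$count_b, count_c = hv$count_c,
      mass_a = hv$mass_a, mass_b = hv$mass_b, mass_c = hv$mass_c,
      transpiration_l = trans_day / 1000,
      supply = wd$ledger$supply, drain = wd$ledger$drain,
      deficit = deficit,
      cum_heat = state$cum_heat, cum_electricity = state$cum_electricity,
      cum_co2 = state$cum_co2, cum_water = state$cum_water)
  }

  daily <- do.call(rbind, daily)
  harvests <- do.call(rbind, harvests)
  water <- do.call(rbind, water)

  resources <- list(electricity = state$cum_electricity,
                    heat = state$cum_heat, co2 = state$cum_co2,
                    water = state$cum_water)
  marketable <- sum(harvests$mass_a + harvests$mass_b)
  yield_kg <- sum(harvests$mass_a + harvests$mass_b + harvests$mass_c)
  fruits <- sum(harvests$count_a + harvests$count_b + harvests$count_c)
  weeks <- as.numeric(sc$end_date - sc$start_date) / 7
  labour_hours <- weeks * (0.008 + 0.0077 * plan$stem_density) +
    0.002 * yield_kg
  income <- compute_income(harvests, sc$prices, sc$start_date)
  ledger <- compute_costs(resources, sc$uprices, plan, labour_hours)
  profit <- net_profit(income, ledger)
  sust <- if (marketable > 0) sustainability_factors(resources, marketable)
          else NULL
  ypt <- yield_at_date(harvests, plan$topping_date)

  structure(list(name = sc$name, daily = daily, harvests = harvests,
                 water = water, aggregates = aggregates,
                 resources = resources, income = income, ledger = ledger,
                 net_profit = profit, sustainability = sust,
                 yield_kg = yield_kg, marketable_yield_kg = marketable,
                 fruits_per_m2 = fruits,
                 yield_prior_to_topping = ypt,
                 aborted_per_m2 = sum(daily$aborted_fruits),
                 labour_hours = labour_hours,
                 flux_extremes = ext, co2_closure_max_err = co2_err,
                 starvation_days = sum(daily$starvation),
                 deficit_days = sum(daily$deficit),
                 scenario = sc),
            class = "simulation_result")
}

#' Cumulative marketable yield up to a date
#'
#' @param harvests harvest data.frame with `date`, `mass_a`, `mass_b`
#' @param date cut-off (inclusive)
#' @return class A + B fresh mass harvested up to `date`, kg/m2
#' @export
yield_at_date <- function(harvests, date) {
  sel <- as.Date(harvests$date) <= as.Date(date)
  sum(harvests$mass_a[sel] + harvests$mass_b[sel])
}

#' Swap one strategy facet between scenarios
#'
#' Returns a new scenario where only the facet-owned parameters of the
#' donor replace the base's: `cropping` moves stem density, prune
#' fractions, topping date and stems per plant; `lighting` moves the lamp
#' window, radiation threshold and the blackout-with-lamps rule; `co2`
#' moves the CO2 setpoint schedule; `climate` (the optional combined facet)
#' moves the temperature schedule together with CO2. Everything else —
#' including the weather — stays with the base compartment.
#'
#' @param base,donor [scenario()] objects
#' @param facet one of "cropping", "lighting", "co2", "climate"
#' @return a new `scenario`
#' @export
swap_strategy <- function(base, donor, facet = c("cropping", "lighting",
                                                 "co2", "climate")) {
  facet <- match.arg(facet)
  s <- base$strategy
  d <- donor$strategy
  if (facet == "cropping") {
    s$cropping$stem_density <- d$cropping$stem_density
    s$cropping$fruit_prune_pattern <- d$cropping$fruit_prune_pattern
    s$cropping$leaf_prune_fraction <- d$cropping$leaf_prune_fraction
    s$cropping$topping_date <- d$cropping$topping_date
    s$cropping$stems_per_plant <- d$cropping$stems_per_plant
  } else if (facet == "lighting") {
    s$light_start <- d$light_start
    s$light_end <- d$light_end
    s$light_threshold <- d$light_threshold
    s$blackout_with_lamps <- d$blackout_with_lamps
  } else if (facet == "co2") {
    s$co2_day <- d$co2_day
    s$co2_night <- d$co2_night
    s$co2_ramp <- d$co2_ramp
  } else {
    s$co2_day <- d$co2_day; s$co2_night <- d$co2_night
    s$co2_ramp <- d$co2_ramp
    s$heat_day <- d$heat_day; s$heat_night <- d$heat_night
    s$vent_offset <- d$vent_offset
  }
  out <- base
  out$strategy <- s
  out$name <- paste0(base$name, "<-", facet, ":", donor$name)
  out
}

#' Swap matrix over a set of scenarios
#'
#' One row per base scenario, one column per donor: each cell is a fresh
#' run of the base with the donor's facet installed. Diagonal cells equal
#' the base runs. Yields are reported prior to topping, evaluated at the
#' earliest topping date of the base/donor pair so both arms cover the same
#' calendar span.
#'
#' @param scenarios named list of [scenario()] objects (>= 2)
#' @param facet facet to swap, see [swap_strategy()]
#' @return list with matrices `yield_prior_to_topping` and `net_profit`
#'   (rows = base, cols = donor) and `long`, a tidy data.frame of all cells
#' @export
swap_matrix <- function(scenarios, facet = "lighting") {
  stopifnot(length(scenarios) >= 2)
  nm <- names(scenarios)
  if (is.null(nm)) nm <- vapply(scenarios, `[[`, "", "name")
  n <- length(scenarios)
  ym <- pm <- matrix(NA_real_, n, n, dimnames = list(base = nm, donor = nm))
  rows <- list()
  for (b in seq_len(n)) for (dn in seq_len(n)) {
    sw <- swap_strategy(scenarios[[b]], scenarios[[dn]], facet)
    res <- run_scenario(sw)
    cut <- min(scenarios[[b]]$strategy$cropping$topping_date,
               scenarios[[dn]]$strategy$cropping$topping_date)
    ym[b, dn] <- yield_at_date(res$harvests, cut)
    pm[b, dn] <- res$net_profit
    rows[[length(rows) + 1]] <- data.frame(
      base = nm[b], donor = nm[dn], facet = facet,
      yield_prior_to_topping = ym[b, dn], net_profit = pm[b, dn],
      marketable_yield = res$marketable_yield_kg)
  }
  list(yield_prior_to_topping = ym, net_profit = pm,
       long = do.call(rbind, rows))
}

#' Validate predicted against reference yields
#'
#' Per-scenario relative error with a pass flag at the stated tolerance;
#' scenarios failing the tolerance can be excluded from downstream swap
#' analysis (as a compartment whose realized season broke the model
#' assumptions would be).
#'
#' @param predicted named numeric vector of model yields, kg/m2
#' @param reference named numeric vector of reference yields, kg/m2 (same
#'   names)
#' @param tolerance relative-error pass tolerance (default 10%)
#' @return data.frame: scenario, predicted, reference, rel_error, pass
#' @export
validate_predictions <- function(predicted, reference, tolerance = 0.1) {
  if (!setequal(names(predicted), names(reference)))
    stop("scenario names do not match between predicted and reference")
  reference <- reference[names(predicted)]
  rel <- abs(predicted - reference) / reference
  data.frame(scenario = names(predicted),
             predicted = as.numeric(predicted),
             reference = as.numeric(reference),
             rel_error = as.numeric(rel),
             pass = as.numeric(rel) <= tolerance, row.names = NULL)
}

#' Re-predict a season from its own recorded climate
#'
#' Closed-loop validation twin: runs the daily crop model over the hourly
#' climate aggregates recorded in a simulation result, with the same
#' cropping plan, and returns the re-predicted marketable yield. Agreement
#' with the original run verifies that the crop model responds only to the
#' recorded climate channels.
#'
#' @param result a `simulation_result`
#' @return list with `marketable_yield_kg` and the re-run `harvests`
#' @export
repredict_from_climate <- function(result) {
  sc <- result$scenario
  plan <- sc$strategy$cropping
  crop <- initial_crop_state(plan, sc$kparams)
  hv <- vector("list", length(result$aggregates))
  for (d in seq_along(result$aggregates)) {
    up <- daily_crop_update(crop, result$aggregates[[d]], plan, sc$kparams)
    crop <- up$crop
    hv[[d]] <- up$harvest
  }
  hv <- do.call(rbind, hv)
  list(marketable_yield_kg = sum(hv$mass_a + hv$mass_b), harvests = hv)
}

#' Scale the light input of a scenario
#'
#' Multiplies natural light (global radiation and PAR) and the lamp photon
#' flux by a common factor — the probe used for light-response and
#' elasticity analyses.
#'
#' @param sc a [scenario()]
#' @param factor light multiplier (> 0)
#' @return the scaled scenario
#' @export
scale_light <- function(sc, factor) {
  stopifnot(factor > 0)
  sc$weather$global_radiation <- sc$weather$global_radiation * factor
  sc$weather$par <- sc$weather$par * factor
  sc$limits$lamp_ppfd <- sc$limits$lamp_ppfd * factor
  sc$name <- paste0(sc$name, " x", factor)
  sc
}

#' Local light elasticity of yield
#'
#' Central finite difference on the log of marketable yield against the log
#' of the light scale: runs the scenario at `1 - delta` and `1 + delta`
#' times its light input and returns
#' `dlog(yield) / dlog(light)`. The rule-of-thumb value for a light-limited
#' greenhouse crop is about 1.
#'
#' @param sc a [scenario()]
#' @param delta relative light perturbation (default 10%; large enough that
#'   discrete fruit-cohort harvests do not dominate the difference)
#' @return list: `elasticity`, `yield_lo`, `yield_hi`
#' @export
light_elasticity <- function(sc, delta = 0.1) {
  lo <- run_scenario(scale_light(sc, 1 - delta))
  hi <- run_scenario(scale_light(sc, 1 + delta))
  y_lo <- lo$marketable_yield_kg
  y_hi <- hi$marketable_yield_kg
  el <- (log(y_hi) - log(y_lo)) / (log(1 + delta) - log(1 - delta))
  list(elasticity = el, yield_lo = y_lo, yield_hi = y_hi)
}
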