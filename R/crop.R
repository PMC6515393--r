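#' High-wire cucumber crop model
#'
#' Source-sink crop model in the tradition of horticultural explanatory
#' models: hourly canopy gross photosynthesis (Beer-law light interception,
#' negative-exponential leaf light response with a CO2- and
#' temperature-dependent maximum) is summed to a daily assimilate pool;
#' after maintenance respiration the pool is partitioned over roots, stem,
#' leaves and fruit cohorts in proportion to their potential growth rates.
#' Fruit cohorts develop with temperature, abort under source limitation,
#' and are harvested by fresh weight into quality classes A/B/C.
#'
#' @name crop
NULL

# 5-point Gauss-Legendre abscissae/weights on [0, 1] for canopy depth
# integration
GAUSS_P <- c(0.0469100770, 0.2307653449, 0.5, 0.7692346551, 0.9530899230)
GAUSS_W <- c(0.1184634425, 0.2393143352, 0.2844444444, 0.2393143352,
             0.1184634425)

#' Crop model parameters
#'
#' @param k_ext canopy light extinction coefficient
#' @param quantum_eff leaf quantum efficiency, mol CO2 per mol photons
#' @param pmax_sat light-saturated leaf photosynthesis at saturating CO2 and
#'   optimum temperature, umol CO2/m2/s
#' @param km_co2 Michaelis constant of the CO2 response, ppm
#' @param t_opt,t_width optimum and width (degC) of the Gaussian temperature
#'   response of Pmax
#' @param dm_fraction fruit dry-matter fraction mapping dry to fresh weight
#' @param growth_conversion assimilate requirement, g CH2O per g dry matter
#' @param maint_coef maintenance respiration at 25 degC, g CH2O per g organ
#'   dry mass per day, named for roots/stem/leaves/fruits
#' @param q10_maint Q10 of maintenance respiration
#' @param sla specific leaf area, m2 per g leaf dry mass
#' @param lai_max leaf area index cap; leaf mass beyond it is removed
#'   (standard lower-leaf removal below the last harvested fruit)
#' @param fruit_dry_target potential fruit dry mass, g per fruit
#' @param harvest_fresh_target harvest trigger fresh weight, g per fruit
#' @param fruit_set_interval thermal time between successive fruit cohorts,
#'   degC d per stem
#' @param t_base base temperature for thermal time, degC
#' @param dev_days_ref fruit growth duration at the 21 degC calibration
#'   midpoint, days
#' @param dev_k exponential temperature sensitivity of development (1/degC);
#'   with the default, durations span roughly 13-22 days between warm
#'   (24-25 degC) and cool (19 degC) regimes
#' @param abort_threshold trailing supply/demand ratio below which young
#'   fruits abort
#' @param abort_window trailing window, days
#' @param abort_young_dev cohorts below this development stage count as
#'   young (abortable)
#' @param sink_scale multiplier on the nominal fruit growth rate giving the
#'   non-limited potential; values above 1 make the canopy source-limited
#'   under typical autumn light, which is the regime the model targets
#' @param veg_potential potential vegetative growth, g DM per stem per day,
#'   named for leaves/stem/roots
#' @param veg_potential_topped same, after topping
#' @param leaf_rate leaf initiation rate, leaves per stem per day
#' @param shape_base baseline of the fruit sink shape function (young-fruit
#'   sink strength relative to peak)
#' @return a `crop_params` list
#' @export
crop_params <- function(k_ext = 0.8, quantum_eff = 0.068, pmax_sat = 45,
                        km_co2 = 250, t_opt = 26, t_width = 14,
                        dm_fraction = 0.035, growth_conversion = 1.39,
                        maint_coef = c(roots = 0.012, stem = 0.010,
                                       leaves = 0.020, fruits = 0.008),
                        q10_maint = 2, sla = 0.03, lai_max = 3.5,
                        fruit_dry_target = 15, harvest_fresh_target = 400,
                        fruit_set_interval = 12, t_base = 10,
                        dev_days_ref = 18.2, dev_k = 0.0868,
                        abort_threshold = 0.6, abort_window = 7,
                        abort_young_dev = 0.25, sink_scale = 1.5,
                        veg_potential = c(leaves = 1.0, stem = 0.7,
                                          roots = 0.25),
                        veg_potential_topped = c(leaves = 0, stem = 0.1,
                                                 roots = 0.1),
                        leaf_rate = 0.35, shape_base = 0.1) {
  p <- as.list(environment())
  # normalize the sink shape so its integral over dev in [0,1] is 1
  p$shape_norm <- 1 / (p$shape_base + 2 / pi)
  p
}

#' Hourly canopy gross photosynthesis
#'
#' Beer-law interception over the LAI with a 5-point Gaussian depth
#' integration; the leaf response is a negative exponential saturating at a
#' CO2- (Michaelis) and temperature- (Gaussian) dependent maximum, with a
#' mild humidity factor. Strictly increasing in PAR and saturating in CO2;
#' zero at zero PAR or zero LAI.
#'
#' @param par PAR above the crop, umol/m2/s
#' @param co2 CO2 concentration, ppm
#' @param temp air temperature, degC
#' @param rh relative humidity, percent
#' @param lai leaf area index, m2/m2
#' @param params a [crop_params()]
#' @return gross assimilation, g CH2O/m2/h
#' @export
hourly_canopy_photosynthesis <- function(par, co2, temp, rh, lai,
                                         params = crop_params()) {
  stopifnot(par >= 0, co2 >= 0, lai >= 0, rh >= 0)
  if (par == 0 || lai == 0) return(0)
  p <- params
  pmax_leaf <- p$pmax_sat * co2 / (co2 + p$km_co2) *
    exp(-((temp - p$t_opt) / p$t_width)^2) *
    (0.85 + 0.15 * min(rh, 100) / 100)
  if (pmax_leaf <= 0) return(0)
  lai_depth <- GAUSS_P * lai
  i_leaf <- p$k_ext * par * exp(-p$k_ext * lai_depth)
  p_leaf <- pmax_leaf * (1 - exp(-p$quantum_eff * i_leaf / pmax_leaf))
  a_umol <- lai * sum(GAUSS_W * p_leaf)          # umol CO2/m2/s
  a_umol * 3600 * 1e-6 * M_CH2O                  # g CH2O/m2/h
}

#' Fruit development rate
#'
#' Exponential temperature response calibrated so fruit growth duration is
#' `dev_days_ref` days at 21 degC and spans roughly 13-22 days between warm
#' and cool regimes. Temperatures outside (0, 45) are clamped with a
#' warning.
#'
#' @param temp mean air temperature, degC
#' @param params a [crop_params()]
#' @return development rate, stage per day (stage in `[0, 1]`)
#' @export
fruit_development_rate <- function(temp, params = crop_params()) {
  if (temp <= 0 || temp >= 45) {
    warning("temperature outside (0, 45) clamped for fruit development")
    temp <- min(max(temp, 0.1), 44.9)
  }
  1 / (params$dev_days_ref * exp(-params$dev_k * (temp - 21)))
}

# relative sink strength of a fruit over its development: baseline plus a
# half-sine peaking mid-development, normalized to integrate to 1
fruit_sink_shape <- function(dev, params) {
  params$shape_norm * (params$shape_base + sin(pi * pmin(dev, 1)))
}

#' Partition an assimilate pool over sinks
#'
#' Proportional allocation by potential growth rates, capped at each sink's
#' potential; any excess spills to the reserve buffer. Exact closure:
#' `pool = sum(allocations) + reserve`.
#'
#' @param pool available assimilates, g CH2O/m2
#' @param potentials potential sink demands, g CH2O/m2 (>= 0)
#' @return list with `alloc` (same length as `potentials`) and `reserve`
#' @export
partition_assimilates <- function(pool, potentials) {
  stopifnot(pool >= 0, all(potentials >= 0))
  total <- sum(potentials)
  if (total == 0 || pool == 0) {
    return(list(alloc = stats::setNames(numeric(length(potentials)),
                                        names(potentials)),
                reserve = pool))
  }
  alloc <- pmin(pool * potentials / total, potentials)
  list(alloc = alloc, reserve = pool - sum(alloc))
}

#' Flag young fruit cohorts for abortion under source limitation
#'
#' When the trailing supply/demand ratio is below the threshold, the
#' youngest non-aborted cohorts are flagged until the projected demand of
#' the remaining cohorts fits the supply. Aborted cohorts stop growing and
#' are excluded from future sink totals and from harvest.
#'
#' @param cohorts cohort data.frame (columns `set_date`, `fruits_per_m2`,
#'   `dev`, `dry_wt`, `aborted`, `demand`)
#' @param supply_demand_ratio trailing-window mean of daily pool over daily
#'   demand
#' @param threshold abortion threshold on the ratio
#' @param young_dev development stage below which a cohort is abortable
#' @return the cohort data.frame with updated `aborted` flags
#' @export
abort_fruits <- function(cohorts, supply_demand_ratio, threshold = 0.6,
                         young_dev = 0.35) {
  stopifnot(supply_demand_ratio >= 0)
  if (supply_demand_ratio >= threshold || nrow(cohorts) == 0) return(cohorts)
  active <- !cohorts$aborted
  total_demand <- sum(cohorts$demand[active])
  supply <- supply_demand_ratio * total_demand
  # youngest first (latest set date)
  candidates <- which(active & cohorts$dev < young_dev)
  candidates <- candidates[order(cohorts$set_date[candidates],
                                 decreasing = TRUE)]
  remaining <- total_demand
  for (i in candidates) {
    if (remaining <= supply) break
    cohorts$aborted[i] <- TRUE
    remaining <- remaining - cohorts$demand[i]
  }
  cohorts
}

#' Classify a harvested fruit by fresh weight
#'
#' Class A above 375 g, class B from 300 to 375 g inclusive (the published
#' ">375" makes the 375 g boundary exclusive for A), class C below 300 g.
#' Defects are not modelled.
#'
#' @param fresh_weight fresh weight per fruit, g (> 0); vectorized
#' @return character vector of "A", "B" or "C"
#' @export
classify_fruit <- function(fresh_weight) {
  if (any(fresh_weight <= 0)) stop("fresh weight must be positive")
  ifelse(fresh_weight > 375, "A", ifelse(fresh_weight >= 300, "B", "C"))
}

#' Light use efficiency
#'
#' Grams of marketable fruit per mol of incident PAR over a window.
#'
#' @param harvest_mass harvested fresh mass over the window, g/m2
#' @param dli light integral over the window, mol/m2 (> 0)
#' @return light use efficiency, g/mol
#' @export
light_use_efficiency <- function(harvest_mass, dli) {
  if (any(dli <= 0)) stop("light integral must be positive (zero-light window undefined)")
  harvest_mass / dli
}

#' Initial crop state
#'
#' Young transplants: small vegetative mass, no fruits.
#'
#' @param plan a [cropping_plan()]
#' @param params a [crop_params()]
#' @return a `crop_state` list
#' @export
initial_crop_state <- function(plan, params = crop_params()) {
  dm <- c(roots = 3, stem = 6, leaves = 12, fruits = 0)
  structure(list(
    stem_density = plan$stem_density,
    dm = dm,
    lai = params$sla * dm[["leaves"]],
    cohorts = data.frame(set_date = as.Date(character()),
                         fruits_per_m2 = numeric(), dev = numeric(),
                         dry_wt = numeric(), aborted = logical(),
                         demand = numeric()),
    leaves_per_stem = 6,
    thermal_time = 0, thermal_since_set = 0, prune_idx = 0L,
    reserve = 0, ratio_history = numeric(), starvation_days = 0L,
    pruned_leaf_dm = 0),
    class = "crop_state")
}

#' Build a daily climate aggregate
#'
#' The crop model consumes hourly climate: 24 entries per channel.
#'
#' @param date calendar date
#' @param par hourly mean PAR above the crop, umol/m2/s (length 24)
#' @param temp hourly mean air temperature, degC (length 24)
#' @param co2 hourly mean CO2, ppm (length 24)
#' @param rh hourly mean relative humidity, percent (length 24)
#' @return a `daily_climate` list with derived `dli` (mol/m2/d) and
#'   `mean_temp`
#' @export
daily_climate_aggregate <- function(date, par, temp, co2, rh) {
  stopifnot(length(par) == 24, length(temp) == 24, length(co2) == 24,
            length(rh) == 24)
  structure(list(date = as.Date(date), par = par, temp = temp, co2 = co2,
                 rh = rh, dli = sum(par) * 3600 / 1e6,
                 mean_temp = mean(temp)),
            class = "daily_climate")
}

empty_harvest <- function(date) {
  data.frame(date = as.Date(date), count_a = 0, count_b = 0, count_c = 0,
             mass_a = 0, mass_b = 0, mass_c = 0)
}

#' Advance the crop one day
#'
#' Computes the daily assimilate pool (sum of 24 hourly canopy
#' photosynthesis rates minus Q10 maintenance respiration, floored at zero
#' with the deficit logged as a starvation day), adds the reserve carried
#' from previous days, partitions it over vegetative sinks and fruit
#' cohorts by relative potential growth rates, advances cohort development,
#' initiates new cohorts per stem per thermal-time interval (thinned by the
#' fruit prune fraction; none after topping), applies source-limited
#' abortion, and harvests cohorts whose fruits reach the target fresh
#' weight, classifying them by weight.
#'
#' @param crop a `crop_state`
#' @param agg a [daily_climate_aggregate()]
#' @param plan a [cropping_plan()]
#' @param params a [crop_params()]
#' @param stress_factor multiplier on the daily pool (1 = no stress); the
#'   irrigation-deficit hook feeds this
#' @return list with `crop` (advanced), `harvest` (one-row harvest
#'   data.frame: per-class counts #/m2 and fresh masses kg/m2) and `diag`
#'   (gross, maintenance, pool, demand, supply/demand ratio, abortions,
#'   starvation flag)
#' @export
daily_crop_update <- function(crop, agg, plan, params = crop_params(),
                              stress_factor = 1) {
  p <- params
  date <- agg$date
  tmean <- agg$mean_temp

  # --- source ---
  gross <- sum(vapply(seq_len(24), function(h)
    hourly_canopy_photosynthesis(agg$par[h], agg$co2[h], agg$temp[h],
                                 agg$rh[h], crop$lai, p), numeric(1)))
  maint <- sum(p$maint_coef * crop$dm) * p$q10_maint^((tmean - 25) / 10)
  starvation <- gross < maint
  pool_new <- max(0, gross - maint) * stress_factor
  pool <- pool_new + crop$reserve

  # --- cohort initiation (thermal time, pruned, stops at topping) ---
  dtt <- max(0, tmean - p$t_base)
  crop$thermal_time <- crop$thermal_time + dtt
  crop$thermal_since_set <- crop$thermal_since_set + dtt
  cohorts <- crop$cohorts
  if (date <= plan$topping_date) {
    while (crop$thermal_since_set >= p$fruit_set_interval) {
      crop$thermal_since_set <- crop$thermal_since_set - p$fruit_set_interval
      crop$prune_idx <- crop$prune_idx + 1L
      pattern <- plan$fruit_prune_pattern
      frac <- pattern[((crop$prune_idx - 1L) %% length(pattern)) + 1L]
      kept <- crop$stem_density * (1 - frac)
      if (kept > 0) {
        cohorts <- rbind(cohorts, data.frame(
          set_date = date, fruits_per_m2 = kept, dev = 0, dry_wt = 0,
          aborted = FALSE, demand = 0))
      }
    }
  }

  # --- sink demands (g CH2O/m2/d) ---
  rate <- fruit_development_rate(tmean, p)
  active <- !cohorts$aborted
  if (nrow(cohorts)) {
    cohorts$demand <- ifelse(active,
      cohorts$fruits_per_m2 * p$sink_scale * p$fruit_dry_target * rate *
        fruit_sink_shape(cohorts$dev, p) * p$growth_conversion, 0)
  }
  veg_pot <- if (date <= plan$topping_date) p$veg_potential
             else p$veg_potential_topped
  veg_demand <- veg_pot * crop$stem_density * p$growth_conversion
  demands <- c(veg_demand, if (nrow(cohorts)) cohorts$demand else NULL)
  total_demand <- sum(demands)

  # --- partition ---
  part <- partition_assimilates(pool, demands)
  alloc <- part$alloc
  crop$reserve <- part$reserve
  alloc_veg <- alloc[1:3]
  alloc_fruit <- if (nrow(cohorts)) alloc[-(1:3)] else numeric(0)

  # --- vegetative growth ---
  leaf_gain <- alloc_veg[["leaves"]] / p$growth_conversion *
    (1 - plan$leaf_prune_fraction)
  crop$pruned_leaf_dm <- crop$pruned_leaf_dm +
    alloc_veg[["leaves"]] / p$growth_conversion * plan$leaf_prune_fraction
  crop$dm[["leaves"]] <- crop$dm[["leaves"]] + leaf_gain
  crop$dm[["stem"]] <- crop$dm[["stem"]] + alloc_veg[["stem"]] / p$growth_conversion
  crop$dm[["roots"]] <- crop$dm[["roots"]] + alloc_veg[["roots"]] / p$growth_conversion
  # lower-leaf removal keeps the canopy at lai_max
  if (p$sla * crop$dm[["leaves"]] > p$lai_max) {
    excess <- crop$dm[["leaves"]] - p$lai_max / p$sla
    crop$dm[["leaves"]] <- p$lai_max / p$sla
    crop$pruned_leaf_dm <- crop$pruned_leaf_dm + excess
  }
  crop$lai <- p$sla * crop$dm[["leaves"]]
  if (date <= plan$topping_date)
    crop$leaves_per_stem <- crop$leaves_per_stem +
      p$leaf_rate * (1 - plan$leaf_prune_fraction)

  # --- fruit growth & development ---
  if (nrow(cohorts)) {
    grow <- ifelse(cohorts$aborted, 0,
                   alloc_fruit / (p$growth_conversion *
                                    pmax(cohorts$fruits_per_m2, 1e-12)))
    cohorts$dry_wt <- cohorts$dry_wt + grow
    cohorts$dev <- pmin(1.2, cohorts$dev + ifelse(cohorts$aborted, 0, rate))
    crop$dm[["fruits"]] <- crop$dm[["fruits"]] +
      sum(alloc_fruit) / p$growth_conversion
  }

  # --- abortion on the trailing supply/demand ratio ---
  ratio_today <- if (total_demand > 0) pool / total_demand else 1
  crop$ratio_history <- utils::tail(c(crop$ratio_history, ratio_today),
                                    p$abort_window)
  ratio <- mean(crop$ratio_history)
  ab0 <- cohorts$aborted
  cohorts <- abort_fruits(cohorts, ratio, p$abort_threshold,
                          p$abort_young_dev)
  aborted_today <- sum(cohorts$aborted) - sum(ab0)
  aborted_fruits_today <- sum(cohorts$fruits_per_m2[cohorts$aborted & !ab0])

  # --- harvest ---
  harvest <- empty_harvest(date)
  if (nrow(cohorts)) {
    fresh <- cohorts$dry_wt / p$dm_fraction
    # a fruit is picked when it crosses the weight target, or when fully
    # developed and still growing; on a zero-assimilate day nothing ripens
    # past the criterion, so nothing new is picked
    ready <- !cohorts$aborted &
      (fresh >= p$harvest_fresh_target | (cohorts$dev >= 1 & grow > 0))
    if (any(ready)) {
      cls <- classify_fruit(pmax(fresh[ready], 1e-6))
      for (k in which(ready)) {
        cl <- tolower(classify_fruit(max(fresh[k], 1e-6)))
        harvest[[paste0("count_", cl)]] <-
          harvest[[paste0("count_", cl)]] + cohorts$fruits_per_m2[k]
        harvest[[paste0("mass_", cl)]] <-
          harvest[[paste0("mass_", cl)]] +
          cohorts$fruits_per_m2[k] * fresh[k] / 1000
      }
      crop$dm[["fruits"]] <- max(0, crop$dm[["fruits"]] -
        sum(cohorts$dry_wt[ready] * cohorts$fruits_per_m2[ready]))
      cohorts <- cohorts[!ready, , drop = FALSE]
    }
    # aborted cohorts are cleaned out once they would have matured
    stale <- cohorts$aborted & cohorts$dev + 0 >= 0 &
      (date - cohorts$set_date) > 40
    if (any(stale)) cohorts <- cohorts[!stale, , drop = FALSE]
  }
  crop$cohorts <- cohorts
  if (starvation) crop$starvation_days <- crop$starvation_days + 1L

  list(crop = crop, harvest = harvest,
       diag = list(gross = gross, maintenance = maint, pool = pool,
                   demand = total_demand, ratio = ratio,
                   alloc_total = sum(alloc), reserve = crop$reserve,
                   aborted_today = aborted_today,
                   aborted_fruits_today = aborted_fruits_today,
                   starvation = starvation))
}
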