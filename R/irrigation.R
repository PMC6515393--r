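#' Irrigation bookkeeping
#'
#' Event-based irrigation under the interval setpoint with closed-loop
#' drain recirculation: supply arrives in fixed shots whenever the elapsed
#' time since the previous turn reaches the interval; uptake follows the
#' transpiration-driven demand (adequate-supply assumption); the surplus
#' drains and is recollected, so net water use equals uptake except under
#' deficit. Daily closure `supply = uptake + drain` is exact.
#'
#' @name irrigation
NULL

#' Initial irrigation bookkeeping state
#'
#' @param shot_size supply per irrigation turn, L/m2
#' @return an `irrigation_state` list
#' @export
initial_irrigation_state <- function(shot_size = 0.1) {
  structure(list(shot_size = shot_size, elapsed_min = 0,
                 day_supply = 0, day_uptake_demand = 0),
            class = "irrigation_state")
}

#' Advance irrigation bookkeeping one control interval
#'
#' @param irr an `irrigation_state`
#' @param interval_setpoint minutes between irrigation turns (> 0)
#' @param transpiration current canopy transpiration, g/m2/h
#' @param dt step, s
#' @return the advanced state; an irrigation event fires when the elapsed
#'   time reaches the interval
#' @export
irrigation_step <- function(irr, interval_setpoint, transpiration, dt = 300) {
  if (interval_setpoint <= 0) stop("irrigation interval must be positive")
  if (irr$shot_size <= 0) stop("shot size must be positive")
  irr$elapsed_min <- irr$elapsed_min + dt / 60
  if (irr$elapsed_min >= interval_setpoint) {
    irr$elapsed_min <- 0
    irr$day_supply <- irr$day_supply + irr$shot_size
  }
  irr$day_uptake_demand <- irr$day_uptake_demand +
    transpiration * dt / 3600 / 1000   # g -> L
  irr
}

#' Close the daily water ledger
#'
#' Uptake is the transpiration-driven demand capped at supply; drain is the
#' remainder (recirculated, so net use = uptake). A day whose supply falls
#' short of demand is flagged as a deficit day; the flag feeds the
#' (default-off) crop stress hook.
#'
#' @param irr an `irrigation_state` at end of day
#' @param date the day
#' @return list with `ledger` (one-row data.frame: supply, uptake, drain,
#'   net_use in L/m2, drain_fraction in percent, deficit flag) and `irr`
#'   (reset for the next day)
#' @export
close_water_day <- function(irr, date) {
  supply <- irr$day_supply
  demand <- irr$day_uptake_demand
  uptake <- min(supply, demand)
  drain <- supply - uptake
  ledger <- data.frame(date = as.Date(date), supply = supply,
                       uptake = uptake, drain = drain, net_use = uptake,
                       drain_fraction = if (supply > 0) 100 * drain / supply
                                        else 0,
                       deficit = demand > supply)
  irr$day_supply <- 0
  irr$day_uptake_demand <- 0
  list(ledger = ledger, irr = irr)
}
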