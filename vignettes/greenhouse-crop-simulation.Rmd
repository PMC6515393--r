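---
title: "Simulating an autumn cucumber season: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating an autumn cucumber season: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hortsim)
```

hortsim simulates a high-tech greenhouse compartment growing a high-wire
cucumber crop through a Dutch autumn season (mid-August to early December),
scores the season economically the way an autonomous-greenhouse benchmark
scores it, and answers counterfactual questions of the form "what would
compartment X have produced under the lighting strategy of compartment Y?".
This vignette explains the models behind those answers, the parameters that
matter, and the choices made where the design was genuinely open.

## The simulation stack

Four layers run in sequence, each feeding the next:

1. **Synthetic weather** (`generate_weather`): 5-minute outside conditions —
   global radiation, PAR, air temperature, relative humidity, wind — plus a
   noisy forecast twin (`make_forecast`).
2. **Control** (`strategy`, `resolve_setpoints`): a strategy (cropping
   choices plus climate schedules) is resolved every 5 minutes into the
   11-element setpoint vector a commercial process computer consumes:
   minimum rail/crop pipe temperatures, heating and ventilation
   temperatures, minimum vent opening, humidity deficit setpoint, two
   screen positions, lamps on/off, CO2 setpoint, irrigation interval.
3. **Climate** (`step_climate`): a lumped energy/vapour/CO2 balance of the
   compartment advances one control interval, honouring the actuator
   capacities (180 + 30 W/m2 pipe heat, 0.3 m2/m2 vent area,
   187 umol/m2/s lamps, 330 g/m2/h fog, 15 g/m2/h CO2), and metering every
   resource.
4. **Crop** (`daily_crop_update`): hourly canopy photosynthesis aggregates
   into a daily assimilate pool that is partitioned over organs by relative
   sink strength; fruit cohorts develop with temperature, abort under
   source limitation, and are harvested by weight into classes A/B/C.

`run_scenario` wires the layers together over a full season;
`swap_strategy`/`swap_matrix` re-run scenarios with exactly one strategy
facet exchanged; the economics layer turns harvest ledgers and resource
meters into income, a cost ledger, net profit and per-kg sustainability
factors.

## Synthetic weather

The generator is a stand-in for measured weather, not a reconstruction of
any particular year: its role is to drive the simulation with a season that
has the right structure. Clear-sky irradiance comes from standard solar
geometry (declination + hour angle) with the Haurwitz model at the default
latitude 52 N. Cloudiness is a daily AR(1) process mapped to a uniform
marginal on [0.15, 1], so day-to-day light integrals vary realistically
while the seasonal envelope declines with the sun; a slow within-day AR
factor adds passing-cloud texture. Temperature has a linear seasonal trend
(17.5 to 5.5 degC over the season), an AR(1) daily anomaly (sd 2 degC) and
a diurnal harmonic whose amplitude grows with clearness. PAR is tied to
global radiation by the fixed horticultural constants 0.47 (PAR fraction)
and 4.6 umol/J.

All stochasticity sits behind one explicit seed; forecasts take a separate
seed so forecast error can be varied independently of the weather itself.
With `noise_scale = 0` the forecast is exactly the time-shifted realized
series — a useful degenerate case for testing control logic.

What the generator does **not** emulate: weather fronts with coherent
multi-day structure in temperature *and* wind *and* radiation, fog
mornings, and extreme events. Tests that pass on this weather therefore
demonstrate correct model mechanics and plausible seasonal aggregates, not
validated performance on any measured year.

## Greenhouse climate

The compartment is one lumped air node (effective height 5 m) with an
additional thermal-mass factor of 8 representing crop, soil and
construction buffering. Energy, vapour and CO2 balances are advanced by
explicit Euler at the 5-minute control interval, with a stability guard:
if the fastest time constant (usually the vapour balance with vents wide
open, ~30 s) falls below twice the step, the step is subdivided.

Controllers mirror a climate computer's habits:

- Heating is proportional (25 W/m2/K) on the shortfall below the heating
  temperature, floored by the minimum-pipe setpoints (a 40 degC rail
  minimum burns heat even while venting — deliberately reproducible
  behaviour) and capped at the pipe peaks.
- Vents open proportionally (15 %/K) above the ventilation temperature,
  plus a small dehumidification opening (up to 6%) when the humidity
  deficit falls below setpoint. The vent flux is
  `leakage + opening x area_ratio x (0.06 wind + 0.03 sqrt |dT|)` m3/m2/s.
- CO2 dosing supplies what the balance needs to hold the setpoint over the
  coming interval (deficit refill + vent loss + canopy uptake), capped at
  15 g/m2/h. This is what makes the limitation behaviour emergent: with
  vents open on a sunny day the cap binds and an 800 ppm setpoint is
  simply never reached, while a closed house holds it exactly.
- The energy screen transmits 75% of light and halves the loss
  coefficient; the blackout screen transmits 1%. Lamps add exactly their
  PPFD to crop-level PAR and draw PPFD/1.8 W/m2 of electricity (HPS
  efficacy), all of which ends as heat.
- Transpiration is a reduced Penman-Monteith form: Beer-law interception
  times (0.55 x absorbed shortwave + 12 x humidity deficit) g/m2/h.

Loss and controller coefficients (cover U 4.5 W/m2/K, the dehumidification
cap, screen-closing rule) were calibrated so a reference-style strategy
holds its temperature setpoints through the season with a heat bill near
100 kWh/m2 — the order reported for efficient autumn compartments. The
ppm/(g/m3) conversion uses the ideal gas law with temperature-dependent air
density.

Resource meters are exact bookkeeping: `cum_heat` advances by pipe power x
dt, electricity by lamp power x on-time, CO2 by injected mass, and the
per-step CO2 closure (storage change = injected - vented - assimilated)
holds to ~1e-16 relative, tested against a 1e-9 bound.

## Crop model

The crop layer is a source-sink model in the explanatory-model tradition.

**Source.** Hourly canopy gross photosynthesis uses Beer-law interception
(k = 0.8) with 5-point Gaussian integration over canopy depth; the leaf
response is a negative exponential with quantum efficiency
0.068 mol CO2/mol photons saturating at a maximum that follows
Michaelis-Menten CO2 kinetics (Km 250 ppm, 45 umol/m2/s at saturation), a
Gaussian temperature optimum at 26 degC and a mild humidity factor. The 24
hourly rates sum to the daily pool; Q10 = 2 maintenance respiration on
organ masses is subtracted first, and a negative balance floors the pool
at zero and logs a starvation day.

**Sinks.** The pool (plus any reserve carried over) is partitioned over
roots, stem, leaves and fruit cohorts in proportion to potential growth
rates, capped at each sink's potential, with the surplus spilling to the
reserve; the closure pool = allocations + reserve is exact and tested.
Each fruit cohort's potential is a normalized half-sine over its
development stage scaled by 1.5 x 15 g dry mass x development rate —
the 1.5 makes the canopy source-limited under autumn light, which is the
regime the whole analysis assumes (and what makes light the binding
factor).

**Development and harvest.** Development rate is exponential in
temperature, calibrated to an 18.2-day fruit growth duration at 21 degC
with durations spanning roughly 13-22 days between warm (24-25 degC) and
cool (19 degC) regimes. A fruit is picked when it crosses the 400 g fresh
target (dry mass / 0.035 dry-matter fraction), or at full development
while still growing; picked fruits classify as A above 375 g, B in
[300, 375], C below — the 375 g boundary is exclusive for A because the
class definition is "above 375".

**Fruit set and pruning.** One potential cohort initiates per stem per
12 degC-d of thermal time above 10 degC, thinned by the plan's prune
fraction (an alternating 50%/67% pattern is expressed as a repeating
sequence). The 12 degC-d interval is a calibration choice: at ~20 degC
mean temperature it produces the ~1 fruit/m2/day flux that a ~40 kg/m2,
~EUR 40/m2 season at EUR 0.30-0.40 per fruit implies; a wider interval
cannot reach the benchmark's fruit counts at any supply level. Topping
halts initiation (and leaf formation) only; standing cohorts finish.

**Abortion.** When the 7-day trailing mean of supply/demand falls below
0.6, the youngest cohorts (development < 0.25) are flagged until the
remaining demand fits the supply. Aborted cohorts stop growing and leave
the sink pool. This single rule produces the qualitative behaviours that
matter: dense crops under low light abort more fruits per m2 than sparse
crops, and a light-starved dense profile wastes most of its fruit load.

**Known limitations.** Water and nutrient limitation of growth are not
modelled (adequate supply is assumed; the irrigation-deficit hook exists
for counterfactuals but defaults off). Fruit defects do not exist, so
class B arises only from weight. Organ-level temperature effects beyond
development rate and Pmax are absent, and the reserve buffer is a simple
carry-over pool without mobilization costs.

## Irrigation

Irrigation is bookkeeping, not hydraulics: a 0.1 L/m2 shot fires whenever
the elapsed time reaches the interval setpoint; uptake equals the
transpiration-driven demand capped at supply; drain is the remainder and
recirculates (closed-loop), so net use equals uptake. Daily closure
supply = uptake + drain is exact. A day whose supply falls short of demand
raises a deficit flag; with the (default-off) stress hook enabled, a
deficit day costs 80% of the next day's pool and aborts cohorts below
development 0.4 — a deliberately blunt instrument whose only role is to
let validation detect a compartment whose realized season broke the
model's assumptions.

## Economics and scoring

Money lives in integer cents per m2; euro amounts are rounded half-up once
on ledger entry, and totals and net profit are exact integer sums — the
published compartment cost tables reproduce to the cent when their
components are fed through the ledger. Weekly class-A prices follow a
deterministic seasonal ramp inside the EUR 0.30-0.40 band; class B earns
85%, class C nothing. Unit resource prices are not published, so defaults
(EUR 0.085/kWh electricity, 0.010/kWh heat, 0.10/kg CO2, 1.65/m3 water,
17.50/h labour) are calibrated to land a simulated season's cost components
in the published order of magnitude; they are configuration, not facts.
Sustainability factors divide each cumulative meter by marketable yield
(class A + B); energy is carried in kWh/kg with a 3.6 MJ/kWh helper since
both units appear in challenge reporting. The challenge score weights net
profit 0.5 and sustainability 0.2 and leaves the 0.3 jury slot as an
external input.

## Counterfactual analysis

`swap_strategy` exchanges exactly one facet between a base and a donor
scenario: *cropping* (stem density, prune fractions, topping date, stems
per plant), *lighting* (lamp window, radiation threshold,
blackout-with-lamps rule) or *co2* (setpoint schedule). Temperature stays
with the base in the co2 facet; a combined temperature+CO2 *climate* facet
is exposed for the broader reading of "climate strategy". Swaps replace
setpoint *schedules* and re-simulate the climate, rather than replaying a
recorded climate trajectory — the alternative would hold the climate
fixed under a different lighting rule, which is physically inconsistent.

Yields in swap matrices are reported *prior to topping*, evaluated at the
earliest topping date of the base/donor pair, so both arms cover the same
calendar span and an early-topping strategy is not penalized for its
shorter tail.

The validation gate (`validate_predictions`) compares model predictions
with realized yields at a 10% relative tolerance and supports excluding
failing compartments from downstream analysis. Its two fixtures are a
closed-loop twin (re-predicting a simulated season from its own recorded
hourly climate, error ~0 by construction — it verifies the crop model
reads only the recorded channels) and an irrigation-blackout season with
the stress hook on, which loses ~15% of yield and is excluded.

## Numerical choices and problem sizes

Explicit Euler with sub-stepping was chosen over an implicit or
exponential integrator for transparency; the guard caps sub-steps at 120.
The CO2 store is floored at 150 ppm with the clamp absorbed into the
assimilation term so mass closure survives the floor. Harvest tie-breaks:
a cohort exactly at the weight target is picked; fruits at the 375 g class
boundary are class B. The analysis scripts run the full 115-day season at
5-minute resolution (33 120 steps) for single-scenario work, and shorten
counterfactual grids (to 1 November, ~22 000 steps) where only orderings
and differences matter; the test suite uses 45-70-day seasons for the same
reason. A full season simulates in roughly 10 s.

## What the tests do and do not show

The suite covers exact arithmetic (economics, conservation budgets),
emergent limitation behaviour (CO2 under venting, actuator caps over a
season), and directional science (yield monotone in light, light
elasticity near 1, density-dependent abortion, temperature-dependent fruit
turnover). All of it runs on synthetic weather and stylized strategies.
None of it demonstrates agreement with any measured compartment season —
the package's quantitative claims are about its own internal consistency
and about orders of magnitude, not about reproducing experimental yield
curves.
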