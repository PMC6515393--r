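# hortsim

Greenhouse climate and high-wire cucumber crop simulation with
strategy-swap counterfactual analysis.

## The problem

Autonomous-greenhouse benchmarks hand several teams identical greenhouse
compartments for one autumn cucumber season and score them on net profit
and resource-use efficiency; the interesting scientific question afterwards
is *attribution* — how much of each compartment's result came from its
lighting strategy, its CO2 dosing, or its cropping choices (stem density,
pruning, topping date)? Answering that requires re-running seasons that
never happened: the same compartment under another team's lighting rule,
everything else held fixed.

hortsim provides that machinery end to end, with no external data: a
seeded generator of Dutch-autumn outside weather, a setpoint-driven lumped
greenhouse climate model with realistic actuator limits, a source-sink
cucumber crop model with fruit cohorts and quality classes, the
challenge's economics (weekly fruit prices, cost ledger in integer cents,
net profit, per-kg sustainability factors), and a counterfactual engine
that exchanges exactly one strategy facet between scenarios and
re-simulates.

It is written for greenhouse crop modellers and for anyone studying
climate-control strategies against a mechanistic benchmark.

## The models in brief

- **Climate**: one lumped air node; explicit-Euler energy/vapour/CO2
  balances at the 5-min control interval (sub-stepped under a stability
  guard); proportional heating/venting controllers; CO2 dosing capped at
  15 g/m2/h so an 800 ppm setpoint is emergently unreachable with vents
  open; lamps add exactly 187 umol/m2/s; every resource metered.
- **Crop**: canopy gross photosynthesis A = LAI * sum_i w_i Pmax (1 -
  exp(-eps k I e^{-k L_i} / Pmax)) summed hourly into a daily pool;
  maintenance respiration (Q10 = 2) subtracted; the remainder partitioned
  over roots/stem/leaves/fruit-cohorts proportionally to potential growth
  rates (allocation_i = pool * p_i / sum p, capped at p_i, surplus to a
  reserve). Fruits develop with temperature (13-22 day durations between
  warm and cool regimes), abort when the 7-day supply/demand ratio drops
  below 0.6, and are picked at 400 g fresh weight into classes A (>375 g),
  B (300-375 g), C (<300 g).
- **Economics**: income = sum over weeks and classes of count x price,
  class B at 85% of class A, class C unpaid; money in integer cents so
  ledger identities are exact.

See the methods vignette
(`vignettes/greenhouse-crop-simulation.Rmd`) for assumptions, parameter
defaults and limitations.

## Worked example

```r
library(hortsim)

sc  <- scenario("reference", reference_grower_strategy(), weather_seed = 11)
res <- run_scenario(sc)
res$marketable_yield_kg   # 23.2  kg/m2 class A+B over the season
res$fruits_per_m2         # 58.75 fruits/m2
res$resources$heat        # 95.6  kWh/m2 heating energy
res$net_profit            # -0.75 EUR/m2 (income 19.86 - costs 20.61)
res$sustainability$heat_per_kg  # 4.11 kWh heat per kg fruit
```

A season of 115 days at 5-minute resolution (33 120 control steps) runs in
about 10 s. The counterfactual question "what would the low-light AiCU
profile have yielded under Sonoma's lighting?":

```r
teams <- team_profile_strategies()
aicu   <- scenario("AiCU",   teams$AiCU,   end_date = "2018-10-23", weather_seed = 11)
sonoma <- scenario("Sonoma", teams$Sonoma, end_date = "2018-10-23", weather_seed = 11)
run_scenario(aicu)$marketable_yield_kg                               # 5.9 kg/m2
run_scenario(swap_strategy(aicu, sonoma, "lighting"))$marketable_yield_kg  # 24.6 kg/m2
```

Only the lamp rule moved; cropping, temperature and CO2 schedules stayed
with AiCU. Exchanging CO2 schedules instead moves yields by at most
~1 kg/m2 across the same profiles — light, not CO2, is the binding factor
in an autumn season.

## The analysis workflow

Numbered drivers under `analysis/` run the full study on synthetic
weather and write tables under `results/`:

| script | what it does |
|---|---|
| `01_weather.R` | generate the season's weather + forecast CSVs |
| `02_baseline_season.R` | full baseline season, frozen run directory |
| `03_team_seasons.R` | six compartments, validation gate (one excluded), partial challenge scores |
| `04_strategy_swaps.R` | cropping/lighting/CO2 swap matrices |
| `05_economics_tables.R` | published cost/income components through the exact ledger |

Run them in order with `Rscript analysis/01_weather.R` etc. (about 6 min
total).

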