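#!/usr/bin/env Rscript
# Simulate the manual-grower baseline compartment over the full season and
# freeze the run: daily climate/crop/water tables, harvest ledger, economic
# and sustainability reports.
#
# Output: results/baseline/ (daily.csv, harvest.csv, water.csv,
#         economics.csv, sustainability.csv, config.yaml)

library(hortsim)

sc <- scenario("reference", reference_grower_strategy(), weather_seed = 11)
res <- run_scenario(sc)
write_run_dir(res, "results/baseline")

cat(sprintf("Baseline season: %.1f kg/m2 fresh (%.1f marketable), %.0f fruits/m2\n",
            res$yield_kg, res$marketable_yield_kg, res$fruits_per_m2))
cat(sprintf("Resources: %.0f kWh/m2 heat, %.0f kWh/m2 electricity, %.1f kg/m2 CO2, %.0f L/m2 water\n",
            res$resources$heat, res$resources$electricity,
            res$resources$co2, res$resources$water))
su <- res$sustainability
cat(sprintf("Per kg fruit: %.2f kWh heat, %.2f kWh electricity, %.2f kg CO2, %.1f L water\n",
            su$heat_per_kg, su$electricity_per_kg, su$co2_per_kg,
            su$water_per_kg))
cat(sprintf("Economics: income %.2f, costs %.2f, net profit %.2f EUR/m2\n",
            res$income, ledger_total(res$ledger), res$net_profit))
cat(sprintf("Season light use efficiency: %.1f g marketable fruit per mol PAR\n",
            light_use_efficiency(1000 * res$marketable_yield_kg,
                                 sum(res$daily$dli))))
cat(sprintf("Aborted fruits: %.1f /m2; starvation days: %d\n",
            res$aborted_per_m2, res$starvation_days))
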