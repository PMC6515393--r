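#!/usr/bin/env Rscript
# Generate the synthetic outside weather for the autumn cucumber season and
# its 24 h forecast twin, and summarise what the season looks like.
#
# Output: results/weather.csv, results/weather_forecast.csv,
#         results/weather_daily.csv

library(hortsim)

dir.create("results", showWarnings = FALSE)

weather <- generate_weather(seed = 11)
forecast <- make_forecast(weather, horizon_h = 24, noise_seed = 12,
                          noise_scale = 1)

write_weather_csv(weather, "results/weather.csv")
utils::write.csv(forecast, "results/weather_forecast.csv",
                 row.names = FALSE, quote = FALSE)

daily <- daily_radiation(weather)
utils::write.csv(daily, "results/weather_daily.csv", row.names = FALSE,
                 quote = FALSE)

cat("Season", format(min(daily$date)), "to", format(max(daily$date)),
    "-", nrow(weather), "five-minute records\n")
cat(sprintf("Outside DLI: first 30 d %.1f mol/m2/d, last 30 d %.1f mol/m2/d\n",
            mean(head(daily$dli, 30)), mean(tail(daily$dli, 30))))
cat(sprintf("Air temperature %.1f..%.1f degC, mean wind %.1f m/s\n",
            min(weather$air_temp), max(weather$air_temp),
            mean(weather$wind_speed)))
cat("The radiation integral falls by a factor",
    sprintf("%.1f", mean(head(daily$dli, 30)) / mean(tail(daily$dli, 30))),
    "over the season: supplemental light decides autumn production.\n")
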