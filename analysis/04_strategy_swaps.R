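#!/usr/bin/env Rscript
# The counterfactual core: exchange one strategy facet at a time (cropping,
# lighting, CO2) between compartments and re-simulate, reporting yield
# prior to topping and net profit for every base x donor pair.
#
# To keep the matrix affordable it runs three contrasting compartments
# (Reference, Sonoma, AiCU) on a season shortened to the 1 November horizon;
# the facet ordering conclusions do not depend on the tail of the season.
#
# Output: results/swap_<facet>.csv and a printed summary.

library(hortsim)

teams <- team_profile_strategies()
end <- "2018-11-01"
scs <- list(
  Reference = scenario("Reference", reference_grower_strategy(),
                       end_date = end, weather_seed = 11),
  Sonoma = scenario("Sonoma", teams$Sonoma, end_date = end,
                    weather_seed = 11),
  AiCU = scenario("AiCU", teams$AiCU, end_date = end, weather_seed = 11))

facet_range <- function(m) {
  gain <- sweep(m$yield_prior_to_topping, 1,
                diag(m$yield_prior_to_topping))
  max(abs(gain))
}

spread <- numeric(0)
for (facet in c("cropping", "lighting", "co2")) {
  m <- swap_matrix(scs, facet = facet)
  write_swap_csv(m, sprintf("results/swap_%s.csv", facet))
  cat("\n==", facet, "swaps: yield prior to topping (kg/m2), base rows x",
      "donor columns ==\n")
  print(round(m$yield_prior_to_topping, 2))
  spread[facet] <- facet_range(m)
}

cat("\nLargest single-swap yield change per facet (kg/m2):\n")
print(round(spread, 2))
if (spread[["lighting"]] > spread[["co2"]])
  cat("Exchanging lighting strategies moves yield far more than exchanging",
      "CO2 strategies:\nlight is the binding factor in the autumn season;",
      "CO2 swaps between already-enriched\ncompartments change little.\n")
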