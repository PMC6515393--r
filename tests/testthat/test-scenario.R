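test_that("scenario runs are deterministic and internally consistent", {
  res <- short_ref_run()
  res2 <- run_scenario(short_ref_scenario())
  expect_equal(res2$daily, res$daily)
  expect_equal(res2$net_profit, res$net_profit)

  # cumulative meters are non-decreasing
  d <- res$daily
  expect_true(all(diff(d$cum_heat) >= 0))
  expect_true(all(diff(d$cum_electricity) >= 0))
  expect_true(all(diff(d$cum_co2) >= 0))
  expect_true(all(diff(d$cum_water) >= 0))
  expect_lte(res$yield_prior_to_topping, res$marketable_yield_kg + 1e-12)

  # cross-file bookkeeping oracle: income and totals recomputed from the
  # harvest ledger
  expect_equal(res$income,
               compute_income(res$harvests, res$scenario$prices,
                              res$scenario$start_date))
  expect_equal(res$net_profit,
               (floor(100 * res$income + 0.5) - res$ledger$total_cents) / 100)
  expect_equal(res$marketable_yield_kg,
               sum(res$harvests$mass_a + res$harvests$mass_b))
  su <- res$sustainability
  expect_equal(su$heat_per_kg,
               res$resources$heat / res$marketable_yield_kg)
})

test_that("season light use efficiency matches independent recomputation", {
  res <- short_ref_run()
  lue <- light_use_efficiency(1000 * res$marketable_yield_kg,
                              sum(res$daily$dli))
  expect_equal(lue, 1000 * sum(res$harvests$mass_a + res$harvests$mass_b) /
                 sum(res$daily$dli))
  expect_gt(lue, 2)     # plausible band for cucumber, g/mol
  expect_lt(lue, 40)
})

test_that("pruning every fruit forces zero yield and negative profit", {
  strat <- reference_grower_strategy()
  strat$cropping$fruit_prune_pattern <- 1
  res <- run_cached("pruned_all",
                    run_scenario(scenario("pruned", strat,
                                          end_date = "2018-09-28",
                                          weather_seed = 11)))
  expect_equal(res$yield_kg, 0)
  expect_equal(res$income, 0)
  expect_lt(res$net_profit, 0)
  expect_null(res$sustainability)
})

test_that("swapping a facet with itself is the identity", {
  base <- short_ref_scenario()
  for (facet in c("cropping", "lighting", "co2")) {
    sw <- swap_strategy(base, base, facet)
    expect_equal(sw$strategy, base$strategy)
  }
  sw <- swap_strategy(base, base, "lighting")
  sw$name <- base$name
  expect_equal(run_scenario(sw)$daily, short_ref_run()$daily)
  expect_error(swap_strategy(base, base, "irrigation"), "arg")
})

test_that("a swap moves only the facet-owned parameters", {
  base <- short_ref_scenario()
  donor <- scenario("donor", team_profile_strategies()$Sonoma,
                    end_date = "2018-10-13", weather_seed = 11)
  sw <- swap_strategy(base, donor, "lighting")
  s <- sw$strategy; b <- base$strategy; d <- donor$strategy
  expect_equal(s$light_start, d$light_start)
  expect_equal(s$light_end, d$light_end)
  expect_equal(s$light_threshold, d$light_threshold)
  # everything else byte-equal with the base
  keep <- setdiff(names(b), c("light_start", "light_end", "light_threshold",
                              "blackout_with_lamps"))
  expect_identical(s[keep], b[keep])
  expect_identical(sw$weather, base$weather)

  sw2 <- swap_strategy(base, donor, "co2")
  expect_equal(sw2$strategy$co2_ramp, d$co2_ramp)
  keep2 <- setdiff(names(b), c("co2_day", "co2_night", "co2_ramp"))
  expect_identical(sw2$strategy[keep2], b[keep2])

  sw3 <- swap_strategy(base, donor, "cropping")
  expect_equal(sw3$strategy$cropping$stem_density, 3.3)
  expect_equal(sw3$strategy$cropping$topping_date, d$cropping$topping_date)
  expect_identical(sw3$strategy[setdiff(names(b), "cropping")],
                   b[setdiff(names(b), "cropping")])
})

test_that("installing a high-light lighting strategy raises yield before
           topping", {
  teams <- team_profile_strategies()
  low <- scenario("AiCU", teams$AiCU, end_date = "2018-10-23",
                  weather_seed = 11)
  high <- scenario("Sonoma", teams$Sonoma, end_date = "2018-10-23",
                   weather_seed = 11)
  base_run <- run_cached("aicu_short", run_scenario(low))
  swapped <- run_cached("aicu_sonoma_light",
                        run_scenario(swap_strategy(low, high, "lighting")))
  cut <- as.Date("2018-10-23")
  expect_gt(yield_at_date(swapped$harvests, cut),
            yield_at_date(base_run$harvests, cut))
})

test_that("the swap matrix equals per-cell brute-force runs with an exact
           diagonal", {
  teams <- team_profile_strategies()
  scs <- list(
    Reference = scenario("Reference", reference_grower_strategy(),
                         end_date = "2018-10-03", weather_seed = 11),
    Sonoma = scenario("Sonoma", teams$Sonoma, end_date = "2018-10-03",
                      weather_seed = 11))
  m <- run_cached("swap_matrix_2x2", swap_matrix(scs, facet = "lighting"))
  # diagonal = base runs
  for (nm in names(scs)) {
    base_res <- run_cached(paste0("swapbase_", nm), run_scenario(scs[[nm]]))
    cut <- scs[[nm]]$strategy$cropping$topping_date
    expect_equal(m$yield_prior_to_topping[nm, nm],
                 yield_at_date(base_res$harvests, cut))
    expect_equal(m$net_profit[nm, nm], base_res$net_profit)
  }
  # off-diagonal cell against an individually constructed swap run
  sw <- swap_strategy(scs$Reference, scs$Sonoma, "lighting")
  cell <- run_scenario(sw)
  cut <- min(scs$Reference$strategy$cropping$topping_date,
             scs$Sonoma$strategy$cropping$topping_date)
  expect_equal(m$yield_prior_to_topping["Reference", "Sonoma"],
               yield_at_date(cell$harvests, cut))
  expect_equal(m$net_profit["Reference", "Sonoma"], cell$net_profit)
})

test_that("validation flags only scenarios whose season broke the model
           assumptions", {
  # twin test: re-predicting a compartment from its own recorded climate
  res <- short_ref_run()
  twin <- repredict_from_climate(res)
  expect_lt(abs(twin$marketable_yield_kg - res$marketable_yield_kg) /
              res$marketable_yield_kg, 0.01)

  # an irrigation blackout (deficit hook on) breaks the 10% tolerance
  black <- short_ref_scenario(
    deficit_hook = TRUE,
    blackout_days = as.Date("2018-09-18") + 0:4)
  black_res <- run_cached("blackout", run_scenario(black))
  expect_gt(black_res$deficit_days, 4)
  predicted <- c(reference = res$marketable_yield_kg,
                 blackout = res$marketable_yield_kg)
  observed <- c(reference = res$marketable_yield_kg,
                blackout = black_res$marketable_yield_kg)
  v <- validate_predictions(predicted, observed, tolerance = 0.1)
  expect_true(v$pass[v$scenario == "reference"])
  expect_false(v$pass[v$scenario == "blackout"])
  kept <- v$scenario[v$pass]
  expect_identical(kept, "reference")
  expect_error(validate_predictions(c(a = 1), c(b = 1)), "names")
})

test_that("run directories freeze enough to reproduce and round-trip", {
  res <- short_ref_run()
  dir <- withr::local_tempdir()
  write_run_dir(res, dir)
  expect_true(all(file.exists(file.path(dir,
    c("daily.csv", "harvest.csv", "water.csv", "economics.csv",
      "sustainability.csv", "config.yaml")))))
  # economics CSV carries the exact identities
  eco <- read.csv(file.path(dir, "economics.csv"))
  tot <- eco$eur_per_m2[eco$item == "total_costs"]
  expect_equal(tot, sum(eco$eur_per_m2[1:6]))
  expect_equal(eco$eur_per_m2[eco$item == "net_profit"],
               eco$eur_per_m2[eco$item == "income"] - tot)
  # frozen config reproduces the identical run
  sc2 <- read_run_config(dir)
  res2 <- run_scenario(sc2)
  expect_equal(res2$daily, res$daily)
  expect_equal(res2$net_profit, res$net_profit)
})
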