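# published cost/income components of the six compartments (EUR/m2)
table2 <- list(
  Reference = list(comp = c(3.74, 8.89, 0.95, 0.59, 0.27, 8.32),
                   income = 43.94, costs = 22.76, profit = 21.18),
  Sonoma = list(comp = c(2.74, 10.97, 0.77, 0.62, 0.25, 9.47),
                income = 49.60, costs = 24.82, profit = 24.78),
  iGrow = list(comp = c(3.74, 8.68, 0.82, 0.55, 0.28, 8.85),
               income = 42.95, costs = 22.92, profit = 20.03),
  deep_greens = list(comp = c(2.29, 9.35, 2.92, 1.00, 0.21, 8.73),
                     income = 31.88, costs = 24.50, profit = 7.38),
  The_Croperators = list(comp = c(2.74, 10.91, 1.40, 0.85, 0.29, 9.48),
                         income = 42.82, costs = 25.67, profit = 17.15),
  AiCU = list(comp = c(2.47, 7.04, 0.70, 0.59, 0.28, 10.03),
              income = 36.21, costs = 21.11, profit = 15.10))

test_that("cost ledgers reproduce every published total and net profit to the
           cent", {
  for (nm in names(table2)) {
    t2 <- table2[[nm]]
    led <- cost_ledger(t2$comp[1], t2$comp[2], t2$comp[3], t2$comp[4],
                       t2$comp[5], t2$comp[6])
    expect_identical(ledger_total(led), t2$costs)
    expect_identical(net_profit(t2$income, led), t2$profit)
  }
})

test_that("class prices follow the 85%/zero rules within the price band", {
  prices <- weekly_price_series(17)
  expect_true(all(prices$price_a >= 0.30 & prices$price_a <= 0.40))
  wk <- which(prices$price_a == 0.40)[1]
  expect_equal(fruit_price("A", wk, prices), 0.40)
  expect_equal(fruit_price("B", wk, prices), 0.34)
  expect_equal(fruit_price("C", wk, prices), 0)
  expect_error(fruit_price("D", 1, prices), "unknown")
  expect_error(weekly_price_series(low = 0.2), "is not TRUE")
  # revealed-weekly mode hides the future
  pr <- weekly_price_series(17, revealed_week = 5)
  expect_true(all(is.na(pr$price_a[6:17])))
  expect_error(fruit_price("A", 7, pr), "no price")
})

test_that("income sums counts times class prices and ignores class C", {
  prices <- weekly_price_series(17)
  expect_equal(compute_income(data.frame(date = as.Date(character()),
                                         count_a = numeric(),
                                         count_b = numeric(),
                                         count_c = numeric()), prices), 0)
  start <- as.Date("2018-08-14")
  one <- data.frame(date = start + 3, count_a = 10, count_b = 0, count_c = 5)
  p1 <- prices$price_a[1]
  expect_equal(compute_income(one, prices, start), 10 * p1)

  # mixed multi-week ledger against a spreadsheet-style oracle
  h <- data.frame(date = start + c(2, 9, 16),
                  count_a = c(3, 5.5, 2), count_b = c(1, 0, 4),
                  count_c = c(2, 2, 2))
  pa <- prices$price_a[1:3]
  half_up <- function(x) floor(100 * x + 0.5)   # cents, half-up
  oracle <- sum(h$count_a * half_up(pa) + h$count_b * half_up(0.85 * pa)) / 100
  expect_equal(compute_income(h, prices, start), oracle, tolerance = 1e-12)
  # monotone in marketable counts, flat in class C
  h2 <- h; h2$count_c <- h2$count_c + 10
  expect_equal(compute_income(h2, prices, start),
               compute_income(h, prices, start))
  h3 <- h; h3$count_a[2] <- h3$count_a[2] + 1
  expect_gt(compute_income(h3, prices, start),
            compute_income(h, prices, start))
})

test_that("resource costs multiply meters by unit prices and scale plant
           costs with density", {
  up <- unit_prices()
  zero <- compute_costs(list(electricity = 0, heat = 0, co2 = 0, water = 0),
                        up, cropping_plan(stem_density = 2.5),
                        labour_hours = 0)
  expect_equal(unname(zero$components_cents[-1]), rep(0L, 5))
  led <- compute_costs(list(electricity = 100, heat = 90, co2 = 6,
                            water = 160), up,
                       cropping_plan(stem_density = 2.5), labour_hours = 0.5)
  expect_equal(led$components_cents[["electricity"]], round(100 * 0.085 * 100))
  dense <- compute_costs(list(electricity = 0, heat = 0, co2 = 0, water = 0),
                         up, cropping_plan(stem_density = 3.6), 0)
  expect_gt(dense$components_cents[["plants_substrate"]],
            zero$components_cents[["plants_substrate"]])
  expect_error(compute_costs(list(electricity = 1), up), "missing resource")
})

test_that("sustainability factors divide meters by marketable yield", {
  r <- list(co2 = 6, electricity = 100, heat = 100, water = 160)
  s <- sustainability_factors(r, 50)
  expect_equal(s$heat_per_kg, 2)
  expect_equal(s$co2_per_kg, 0.12)
  s2 <- sustainability_factors(r, 100)
  expect_equal(s2$heat_per_kg, s$heat_per_kg / 2)
  expect_equal(s2$water_per_kg, s$water_per_kg / 2)
  expect_error(sustainability_factors(r, 0), "undefined")
  expect_equal(kwh_to_mj(1), 3.6)
})

test_that("the challenge score weights profit 50%, sustainability 20% and
           leaves 30% to the jury slot", {
  expect_equal(challenge_score(0, 0), 0)
  expect_equal(challenge_score(1, 1), 0.7)
  expect_equal(challenge_score(1, 1, jury_component = 1), 1)
  expect_error(challenge_score(1.2, 0), "\\[0, 1\\]")
  profits <- c(21.18, 24.78, 20.03, 7.38, 17.15, 15.10)
  comp <- rank_normalize(profits)
  expect_equal(comp[which.max(profits)], 1)
  expect_equal(comp[which.min(profits)], 0)
})
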