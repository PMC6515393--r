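Package: hortsim
Title: Greenhouse Climate and High-Wire Cucumber Crop Simulation with
    Strategy-Swap Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A lumped greenhouse climate simulator (energy, vapour and CO2
    balances with realistic actuator limits), an assimilate-partitioning
    cucumber crop model with fruit cohorts, quality classification and
    harvest bookkeeping, horticultural economics (weekly fruit prices, cost
    ledger in integer cents, net profit) and per-kg sustainability factors,
    plus a counterfactual engine that swaps cropping, lighting or CO2
    strategy facets between full-season scenarios. Includes a seeded
    synthetic generator for Dutch-autumn outside weather and its noisy
    forecast twin, so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
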