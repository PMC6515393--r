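#' Run directories and tabular output
#'
#' Every simulation can be frozen to a self-describing run directory: daily
#' climate/crop/water CSVs, the economic and sustainability reports, and a
#' YAML snapshot of the scenario configuration (strategy, seeds, season)
#' sufficient to reproduce the run byte-for-byte.
#'
#' @name io
NULL

#' Write a simulation result to a run directory
#'
#' @param result a `simulation_result`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_run_dir <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$daily, file.path(dir, "daily.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(result$harvests, file.path(dir, "harvest.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(result$water, file.path(dir, "water.csv"),
                   row.names = FALSE, quote = FALSE)
  eco <- data.frame(
    item = c("plants_substrate", "electricity", "heating", "co2", "water",
             "labour", "total_costs", "income", "net_profit"),
    eur_per_m2 = c(result$ledger$components_cents / 100,
                   ledger_total(result$ledger), result$income,
                   result$net_profit))
  utils::write.csv(eco, file.path(dir, "economics.csv"), row.names = FALSE,
                   quote = FALSE)
  if (!is.null(result$sustainability)) {
    su <- result$sustainability
    utils::write.csv(data.frame(factor = names(unclass(su)),
                                value = as.numeric(unclass(su))),
                     file.path(dir, "sustainability.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  sc <- result$scenario
  cfg <- list(name = sc$name,
              start_date = format(sc$start_date),
              end_date = format(sc$end_date),
              weather_seed = sc$weather_seed, latitude = sc$latitude,
              shot_size = sc$shot_size, deficit_hook = sc$deficit_hook,
              strategy = local({
                x <- unclass(sc$strategy)
                x$cropping <- unclass(x$cropping)
                x$cropping$topping_date <- format(x$cropping$topping_date)
                x$cropping$end_date <- format(x$cropping$end_date)
                x
              }))
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Rebuild a scenario from a frozen run configuration
#'
#' Reads `config.yaml` from a run directory and reconstructs the scenario
#' (weather regenerated from the frozen seed), so the run can be repeated
#' identically.
#'
#' @param dir a run directory written by [write_run_dir()]
#' @return a [scenario()]
#' @export
read_run_config <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  st <- cfg$strategy
  cp <- do.call(cropping_plan, st$cropping)
  st$cropping <- NULL
  strat <- do.call(strategy, c(list(cropping = cp), st))
  scenario(cfg$name, strat, start_date = cfg$start_date,
           end_date = cfg$end_date, weather_seed = cfg$weather_seed,
           latitude = cfg$latitude, shot_size = cfg$shot_size,
           deficit_hook = cfg$deficit_hook)
}

#' Write a swap matrix to CSV
#'
#' @param swap result of [swap_matrix()]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_swap_csv <- function(swap, path) {
  utils::write.csv(swap$long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
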