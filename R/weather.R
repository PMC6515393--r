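#' Synthetic Dutch-autumn weather generation
#'
#' Seeded generator for outside weather on a uniform 5-minute grid, emulating
#' the measured outside channels a greenhouse process computer exchanges:
#' global radiation, PAR, air temperature, relative humidity and wind speed,
#' plus a noisy "forecast" twin of those channels. The target season is a
#' Dutch autumn cucumber cycle (mid-August to early December at 52 degrees N):
#' declining day length, daily radiation integrals falling over the season,
#' temperatures roughly 0-25 degC, variable cloudiness and wind.
#'
#' @name weather
NULL

# Run code with a private RNG stream so generators are deterministic per seed
# without disturbing the caller's RNG state.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Default weather generator parameters
#'
#' All stochastic structure of the generator sits behind these parameters.
#' Cloudiness is a first-order autoregressive daily factor with a uniform
#' marginal on `[cloud_min, 1]`; the within-day shape scales the clear-sky
#' curve. Temperature has a linear seasonal trend, a daily AR(1) anomaly and
#' a diurnal harmonic peaking mid-afternoon.
#'
#' @param cloud_min lower bound of the daily cloudiness factor (dimensionless)
#' @param cloud_phi day-to-day AR(1) coefficient of the cloudiness process
#' @param temp_start,temp_end seasonal mean air temperature at season start
#'   and end, degC
#' @param temp_anom_sd,temp_anom_phi daily temperature anomaly AR(1)
#'   stationary sd (degC) and coefficient
#' @param diurnal_amp_base,diurnal_amp_clear diurnal temperature amplitude,
#'   degC: base plus a clear-sky-weighted extra
#' @param wind_mean_log,wind_sd_log,wind_phi lognormal daily wind parameters
#' @param rh_base mean relative humidity, percent
#' @param radiation_scale multiplier on the clear-sky envelope (must be > 0)
#' @return named list of generator parameters
#' @export
weather_params <- function(cloud_min = 0.15, cloud_phi = 0.5,
                           temp_start = 17.5, temp_end = 5.5,
                           temp_anom_sd = 2.0, temp_anom_phi = 0.6,
                           diurnal_amp_base = 2.0, diurnal_amp_clear = 2.5,
                           wind_mean_log = 1.1, wind_sd_log = 0.45,
                           wind_phi = 0.6, rh_base = 82,
                           radiation_scale = 1.0) {
  if (radiation_scale <= 0) stop("radiation_scale must be positive")
  if (cloud_min < 0 || cloud_min >= 1) stop("cloud_min must be in [0, 1)")
  if (abs(cloud_phi) >= 1 || abs(temp_anom_phi) >= 1 || abs(wind_phi) >= 1)
    stop("AR(1) coefficients must have modulus < 1")
  as.list(environment())
}

#' Solar elevation and clear-sky global radiation
#'
#' Standard solar geometry (declination + hour angle) with the Haurwitz
#' clear-sky model. Timestamps are interpreted as local solar time.
#'
#' @param timestamp POSIXct, UTC
#' @param latitude degrees north
#' @return `solar_elevation`: sine of the solar elevation (clamped at 0);
#'   `clear_sky_radiation`: clear-sky global radiation, W/m2
#' @export
solar_elevation <- function(timestamp, latitude) {
  doy <- as.numeric(strftime(timestamp, "%j", tz = "UTC"))
  hour <- as.numeric(strftime(timestamp, "%H", tz = "UTC")) +
    as.numeric(strftime(timestamp, "%M", tz = "UTC")) / 60
  decl <- 23.45 * pi / 180 * sin(2 * pi * (284 + doy) / 365)
  lat <- latitude * pi / 180
  hour_angle <- pi / 12 * (hour - 12)
  sin_el <- sin(lat) * sin(decl) + cos(lat) * cos(decl) * cos(hour_angle)
  pmax(0, sin_el)
}

#' @rdname solar_elevation
#' @export
clear_sky_radiation <- function(timestamp, latitude) {
  sin_el <- solar_elevation(timestamp, latitude)
  ifelse(sin_el > 0, 1098 * sin_el * exp(-0.057 / sin_el), 0)
}

#' Generate a synthetic outside weather series
#'
#' Produces a complete 5-minute series from `start_date` 00:00 to `end_date`
#' 00:00 (inclusive). Radiation is the clear-sky envelope at `latitude`
#' modulated by an autocorrelated daily cloudiness factor and a slowly
#' varying within-day factor; PAR is derived from global radiation with the
#' fixed conversion `0.47 x 4.6 umol/J`. Deterministic for a fixed seed.
#'
#' @param start_date,end_date season bounds (Date or "YYYY-MM-DD")
#' @param latitude degrees north (default 52, central Netherlands)
#' @param seed integer seed for all stochastic components
#' @param params generator parameters, see [weather_params()]
#' @return a `weather_series` data.frame with columns `timestamp`,
#'   `step_index`, `global_radiation`, `par`, `air_temp`, `rel_humidity`,
#'   `wind_speed`, plus `cloud_factor` (the realized daily cloudiness,
#'   repeated per record) for diagnostic use
#' @export
generate_weather <- function(start_date = "2018-08-14",
                             end_date = "2018-12-07",
                             latitude = 52, seed = 1,
                             params = weather_params()) {
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  if (end_date <= start_date) stop("end_date must be after start_date")

  t0 <- as.POSIXct(paste(start_date, "00:00:00"), tz = "UTC")
  t1 <- as.POSIXct(paste(end_date, "00:00:00"), tz = "UTC")
  ts <- seq(t0, t1, by = 300)
  n <- length(ts)
  n_days <- as.integer(end_date - start_date)  # last record belongs to day n_days+1
  day_index <- pmin(n_days + 1L, as.integer(floor(as.numeric(ts - t0, units = "days"))) + 1L)

  with_local_seed(seed, {
    p <- params

    # daily cloudiness: latent standard-normal AR(1), mapped through pnorm to
    # a uniform marginal on [cloud_min, 1]
    nd <- n_days + 1L
    z <- numeric(nd)
    z[1] <- stats::rnorm(1)
    for (d in seq_len(nd - 1))
      z[d + 1] <- p$cloud_phi * z[d] + sqrt(1 - p$cloud_phi^2) * stats::rnorm(1)
    cloud_day <- p$cloud_min + (1 - p$cloud_min) * stats::pnorm(z)

    # slow within-day modulation of the cloud field
    w <- stats::filter(stats::rnorm(n, sd = sqrt(1 - 0.98^2)), 0.98,
                       method = "recursive", init = stats::rnorm(1))
    intraday <- pmin(1.6, pmax(0.4, 1 + 0.15 * as.numeric(w)))

    clear <- p$radiation_scale * clear_sky_radiation(ts, latitude)
    global <- pmax(0, clear * cloud_day[day_index] * intraday)

    # temperature: seasonal linear trend + daily anomaly + diurnal harmonic
    frac <- (day_index - 1) / max(1, nd - 1)
    t_season <- p$temp_start + (p$temp_end - p$temp_start) * frac
    za <- numeric(nd)
    za[1] <- stats::rnorm(1)
    for (d in seq_len(nd - 1))
      za[d + 1] <- p$temp_anom_phi * za[d] +
        sqrt(1 - p$temp_anom_phi^2) * stats::rnorm(1)
    anom <- p$temp_anom_sd * za
    amp <- p$diurnal_amp_base +
      p$diurnal_amp_clear * (cloud_day - p$cloud_min) / (1 - p$cloud_min)
    hour <- as.numeric(ts - t0, units = "hours") %% 24
    micro <- stats::filter(stats::rnorm(n, sd = 0.3 * sqrt(1 - 0.9^2)), 0.9,
                           method = "recursive")
    air_temp <- t_season + anom[day_index] +
      amp[day_index] * cos(2 * pi * (hour - 14) / 24) + as.numeric(micro)

    # relative humidity: high at night / under cloud, reduced by the diurnal
    # temperature excursion
    rh_noise <- stats::rnorm(nd, sd = 4)
    rel_humidity <- pmin(100, pmax(35,
      p$rh_base - 1.8 * (air_temp - (t_season + anom[day_index])) +
        rh_noise[day_index] - 6 * (cloud_day[day_index] - 0.5)))

    # wind: lognormal daily level with within-day AR noise
    zw <- numeric(nd)
    zw[1] <- stats::rnorm(1)
    for (d in seq_len(nd - 1))
      zw[d + 1] <- p$wind_phi * zw[d] + sqrt(1 - p$wind_phi^2) * stats::rnorm(1)
    wind_day <- exp(p$wind_mean_log + p$wind_sd_log * zw)
    wmicro <- stats::filter(stats::rnorm(n, sd = 0.2 * sqrt(1 - 0.95^2)), 0.95,
                            method = "recursive")
    wind_speed <- pmax(0.2, wind_day[day_index] * (1 + as.numeric(wmicro)))

    out <- data.frame(
      timestamp = ts,
      step_index = seq_len(n) - 1L,
      global_radiation = global,
      par = par_from_global(global),
      air_temp = air_temp,
      rel_humidity = rel_humidity,
      wind_speed = wind_speed,
      cloud_factor = cloud_day[day_index]
    )
    attr(out, "latitude") <- latitude
    attr(out, "start_date") <- start_date
    attr(out, "end_date") <- end_date
    attr(out, "seed") <- seed
    class(out) <- c("weather_series", "data.frame")
    out
  })
}

#' Build a noisy forecast twin of a weather series
#'
#' The forecast at time t for horizon h is the realized value at t + h plus
#' autocorrelated noise; with `noise_scale = 0` the forecast equals the
#' time-shifted realized series exactly. Records whose target time lies
#' beyond the series end form a truncated tail flagged `truncated = TRUE`
#' (forecast values NA there).
#'
#' @param weather a `weather_series`
#' @param horizon_h forecast horizon, hours (> 0)
#' @param noise_seed seed for the forecast noise (separate from the weather
#'   seed)
#' @param noise_scale multiplier on the per-channel error sd; the stationary
#'   forecast error sd per channel is `noise_scale` times
#'   c(radiation 30 W/m2, temp 1 degC, rh 5 pct, wind 0.6 m/s)
#' @return data.frame with `timestamp`, forecast channels
#'   (`global_radiation_fc`, `air_temp_fc`, `rel_humidity_fc`,
#'   `wind_speed_fc`) and `truncated`
#' @export
make_forecast <- function(weather, horizon_h = 24, noise_seed = 2,
                          noise_scale = 1) {
  stopifnot(inherits(weather, "weather_series"))
  if (horizon_h <= 0) stop("horizon_h must be positive")
  k <- as.integer(round(horizon_h * 12))
  n <- nrow(weather)
  shift <- function(x) c(x[(k + 1):n], rep(NA_real_, min(k, n)))[seq_len(n)]
  base_sd <- c(global_radiation = 30, air_temp = 1, rel_humidity = 5,
               wind_speed = 0.6)

  with_local_seed(noise_seed, {
    phi <- 0.95
    noise <- function(sd) {
      if (sd == 0) return(numeric(n))
      as.numeric(stats::filter(stats::rnorm(n, sd = sd * sqrt(1 - phi^2)),
                               phi, method = "recursive",
                               init = stats::rnorm(1, sd = sd)))
    }
    fc <- data.frame(
      timestamp = weather$timestamp,
      step_index = weather$step_index,
      global_radiation_fc = pmax(0, shift(weather$global_radiation) +
                                   noise(noise_scale * base_sd[["global_radiation"]])),
      air_temp_fc = shift(weather$air_temp) +
        noise(noise_scale * base_sd[["air_temp"]]),
      rel_humidity_fc = pmin(100, pmax(0, shift(weather$rel_humidity) +
                                         noise(noise_scale * base_sd[["rel_humidity"]]))),
      wind_speed_fc = pmax(0, shift(weather$wind_speed) +
                             noise(noise_scale * base_sd[["wind_speed"]])),
      truncated = is.na(shift(weather$air_temp))
    )
    attr(fc, "horizon_h") <- horizon_h
    attr(fc, "noise_scale") <- noise_scale
    class(fc) <- c("forecast_series", "data.frame")
    fc
  })
}

#' Daily light integral of a weather or PAR series
#'
#' @param par PAR, umol/m2/s, on a uniform grid
#' @param dt grid spacing, seconds
#' @return DLI, mol/m2/d aggregated over the whole vector
#' @export
dli_from_par <- function(par, dt = 300) sum(par, na.rm = TRUE) * dt / 1e6

#' Daily radiation integrals of a weather series
#'
#' @param weather a `weather_series`
#' @return data.frame with `date`, `radiation_integral` (J/cm2/d, matching
#'   the channel convention of greenhouse process computers) and `dli`
#'   (mol PAR/m2/d)
#' @export
daily_radiation <- function(weather) {
  date <- as.Date(weather$timestamp)
  rad <- tapply(weather$global_radiation, date, function(x) sum(x) * 300 / 1e4)
  dli <- tapply(weather$par, date, function(x) sum(x) * 300 / 1e6)
  data.frame(date = as.Date(names(rad)),
             radiation_integral = as.numeric(rad),
             dli = as.numeric(dli), row.names = NULL)
}

#' Read and write weather CSV files
#'
#' One row per 5-minute record, ISO-8601 timestamps, plus a 0-based step
#' index. Round-trips through [read_weather_csv()].
#'
#' @param weather a `weather_series`
#' @param path file path
#' @return `write_weather_csv` returns `path` invisibly;
#'   `read_weather_csv` returns a `weather_series`
#' @export
write_weather_csv <- function(weather, path) {
  df <- as.data.frame(weather)
  df$timestamp <- strftime(df$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_weather_csv
#' @export
read_weather_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$timestamp <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%SZ",
                             tz = "UTC")
  attr(df, "start_date") <- as.Date(df$timestamp[1])
  attr(df, "end_date") <- as.Date(df$timestamp[nrow(df)])
  class(df) <- c("weather_series", "data.frame")
  df
}
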