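#' Synthetic outside weather for a greenhouse season
#'
#' Generates a seeded, 5-minute-resolution outside weather series with the
#' statistical structure the twin assumes: clear-sky global radiation from
#' solar geometry attenuated by a first-order autoregressive cloudiness
#' process, air temperature as seasonal trend + diurnal cycle + slow
#' autoregressive noise, and independent relative-humidity and wind noise
#' processes. It stands in for the outside weather sensors of a Dutch site;
#' it is not a reanalysis product (see the methods vignette for the fidelity
#' limits).
#'
#' @param start_date,end_date `Date` (or coercible). The series covers
#'   `start_date` 00:00 through `end_date` 23:55 inclusive.
#' @param latitude degrees north, in `[40, 60]`. Default 52.0 (Bleiswijk).
#' @param seed integer; identical seeds give bitwise-identical series.
#' @param cloud_persistence lag-one-day autocorrelation of the cloudiness
#'   process, in `[0, 1)`. Default 0.6.
#' @return a `ghw_weather` data.frame with columns `timestamp` (POSIXct, local
#'   solar time encoded as UTC), `global_radiation` (W/m2), `par_outside`
#'   (umol/m2/s), `temp_out` (degC), `rh_out` (%), `wind` (m/s).
#' @examples
#' w <- generate_weather("2019-12-16", "2019-12-22", seed = 1)
#' range(w$global_radiation)
#' @export
generate_weather <- function(start_date, end_date, latitude = 52.0, seed = 1L,
                             cloud_persistence = 0.6) {
  start_date <- as.Date(start_date); end_date <- as.Date(end_date)
  if (!(start_date < end_date)) stopf("start_date (%s) must precede end_date (%s)",
                                      start_date, end_date)
  if (latitude < 40 || latitude > 60) stopf("latitude %.1f outside supported band [40, 60]", latitude)
  if (cloud_persistence < 0 || cloud_persistence >= 1)
    stopf("cloud_persistence must be in [0, 1)")

  t0 <- as.POSIXct(paste(start_date, "00:00:00"), tz = "UTC")
  t1 <- as.POSIXct(paste(end_date, "23:55:00"), tz = "UTC")
  ts <- seq(t0, t1, by = 300)
  n <- length(ts)
  elev <- solar_elevation(ts, latitude)
  gcs <- clearsky_radiation(elev)
  hod <- as.numeric(ts - trunc(ts, "days"), units = "hours")
  doy <- as.integer(strftime(ts, "%j", tz = "UTC"))

  with_seed(seed, {
    # cloudiness: AR(1) latent Gaussian, logistic-mapped to cover in [0,1]
    rho_c <- cloud_persistence^(1 / 288)
    z <- ar1_series(n, rho_c, sd_stat = 1.0)
    cover <- stats::plogis(z - 0.15)
    atten <- 1 - 0.52 * cover   # mean ~0.77 all-sky/clear-sky: a bright season

    t_season <- 10 + 7.5 * cos(2 * pi * (doy - 196) / 365.25)
    amp <- clamp(2.5 + (t_season - 2.5) / 6, 1.5, 5)
    t_noise <- ar1_series(n, exp(-300 / (36 * 3600)), sd_stat = 2.0)
    temp_out <- t_season + amp * cos(2 * pi * (hod - 15) / 24) + t_noise

    g <- gcs * atten
    rh_noise <- ar1_series(n, exp(-300 / (6 * 3600)), sd_stat = 4)
    rh <- clamp(90 - 1.5 * (temp_out - t_season) - 0.025 * g + rh_noise, 35, 100)
    wind <- pmax(0.2, 3.5 + ar1_series(n, exp(-300 / (12 * 3600)), sd_stat = 1.8))
  })

  out <- data.frame(
    timestamp = ts,
    global_radiation = g,
    par_outside = par_from_global(g),
    temp_out = temp_out,
    rh_out = rh,
    wind = wind
  )
  structure(out,
            class = c("ghw_weather", "data.frame"),
            latitude = latitude, seed = seed,
            cloud_persistence = cloud_persistence)
}

# stationary AR(1) with given per-step coefficient and stationary sd
ar1_series <- function(n, rho, sd_stat) {
  e <- rnorm(n, sd = sd_stat * sqrt(1 - rho^2))
  x <- numeric(n)
  x[1] <- rnorm(1, sd = sd_stat)
  if (n > 1) for (i in 2:n) x[i] <- rho * x[i - 1] + e[i]
  x
}

#' Convert global radiation to photosynthetically active radiation
#'
#' Linear conversion from global horizontal irradiance (W/m2) to PAR photon
#' flux (umol/m2/s). The default factor 1.0 umol/s per W of global radiation
#' combines the ~47% PAR energy fraction of sunlight with ~2.1 umol/J within
#' the PAR band.
#'
#' @param global_radiation W/m2, non-negative.
#' @param factor umol PAR per J global radiation.
#' @return PAR in umol/m2/s.
#' @export
par_from_global <- function(global_radiation, factor = 1.0) {
  if (any(global_radiation < 0)) stopf("global_radiation must be non-negative")
  factor * global_radiation
}

#' Daily radiation integrals of a weather series
#'
#' @param weather a `ghw_weather` data.frame.
#' @return data.frame with `date` and `radiation_MJ` (MJ/m2/day).
#' @export
daily_radiation <- function(weather) {
  d <- as.Date(weather$timestamp)
  mj <- tapply(weather$global_radiation * 300 / 1e6, d, sum)
  data.frame(date = as.Date(names(mj)), radiation_MJ = as.numeric(mj),
             row.names = NULL)
}

#' Write / read a weather series as CSV
#'
#' Column layout is stable: `timestamp` (ISO-8601, UTC-encoded local solar
#' time), `global_radiation`, `par_outside`, `temp_out`, `rh_out`, `wind`.
#'
#' @param weather a `ghw_weather` data.frame.
#' @param path file path.
#' @return `read_weather_csv` returns a `ghw_weather` data.frame.
#' @export
write_weather_csv <- function(weather, path) {
  out <- as.data.frame(weather)
  out$timestamp <- strftime(out$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_weather_csv
#' @export
read_weather_csv <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "global_radiation", "par_outside", "temp_out", "rh_out", "wind")
  if (!all(need %in% names(x))) stopf("weather CSV missing columns: %s",
                                      paste(setdiff(need, names(x)), collapse = ", "))
  x$timestamp <- as.POSIXct(x$timestamp, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  structure(x, class = c("ghw_weather", "data.frame"))
}
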