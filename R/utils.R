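#' @useDynLib tomatotwin, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm coef cor lm complete.cases
#' @importFrom utils read.csv write.csv head tail
NULL

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded at `seed` and restores the previous
#' RNG state afterwards, so seeded generators do not disturb the caller's
#' random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Solar elevation angle
#'
#' Solar elevation for a time series at a given latitude, on the local solar
#' time convention (no equation-of-time or longitude correction; solar noon is
#' 12:00 by definition, matching the schedule clock used everywhere else in
#' the package).
#'
#' @param times POSIXct (UTC-encoded local solar time).
#' @param latitude degrees north.
#' @return elevation in degrees (negative below the horizon).
#' @export
solar_elevation <- function(times, latitude) {
  doy <- as.integer(strftime(times, "%j", tz = "UTC"))
  hod <- as.numeric(times - trunc(times, "days"), units = "hours")
  decl <- -23.45 * cos(2 * pi * (doy + 10) / 365.25)
  lat_r <- latitude * pi / 180
  dec_r <- decl * pi / 180
  ha <- (hod - 12) * 15 * pi / 180
  sin_el <- sin(lat_r) * sin(dec_r) + cos(lat_r) * cos(dec_r) * cos(ha)
  asin(clamp(sin_el, -1, 1)) * 180 / pi
}

#' Clear-sky global radiation (Haurwitz)
#'
#' @param elevation_deg solar elevation, degrees.
#' @return global horizontal irradiance, W/m2 (0 when the sun is down).
#' @export
clearsky_radiation <- function(elevation_deg) {
  s <- sin(pmax(elevation_deg, 0) * pi / 180)
  ifelse(elevation_deg > 0, 1098 * s * exp(-0.057 / pmax(s, 1e-6)), 0)
}

# Saturation absolute humidity of air (g water / m3) at temperature T (degC);
# Magnus saturation pressure over ideal-gas vapour density.
sat_abs_humidity <- function(temp_c) {
  es <- 611.2 * exp(17.62 * temp_c / (temp_c + 243.12)) # Pa
  es / (461.5 * (temp_c + 273.15)) * 1000
}

# 1 ppm CO2 ~ 1.83 mg/m3 at greenhouse conditions (44 g/mol, 24.0 L/mol).
CO2_PPM_TO_G_M3 <- 44 / 24.0 / 1000

# Season week index (1-based, 7-day blocks from the season start date).
season_week <- function(dates, start_date) {
  pmax(1L, 1L + (as.integer(as.Date(dates) - as.Date(start_date)) %/% 7L))
}

n_season_weeks <- function(start_date, end_date) {
  as.integer(ceiling((as.numeric(as.Date(end_date) - as.Date(start_date)) + 1) / 7))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
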