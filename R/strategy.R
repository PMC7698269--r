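#' Construct a setpoint schedule
#'
#' A schedule is the open-loop control vocabulary of the challenge: a daily
#' day/night template plus a per-week supplemental-lighting profile, expanded
#' lazily to 5-minute slots by [expand_schedule()]. "Day" slots are those with
#' lamps scheduled on or the sun above the horizon. The lamp block of each day
#' is centred on solar noon; LED power is hard-coupled to HPS power (LEDs can
#' only run when the HPS group is on).
#'
#' @param season_start,season_end season calendar (`Date`).
#' @param weekly_hours lamp hours per day, one entry per season week
#'   (recycled from a scalar).
#' @param led_on use the LED group whenever lamps are on.
#' @param led_channels named percentages (0-100) for the `blue`, `red`,
#'   `farred`, `white` LED channels.
#' @param t_day,t_night heating-line setpoints, degC.
#' @param vent_offset ventilation-line offset above the heating line, degC.
#' @param min_rail_pipe,min_crop_pipe minimum pipe temperatures, degC.
#' @param min_vent_opening minimum window opening, %.
#' @param screen_energy_night energy-screen position at night, %.
#' @param screen_weeks last season week with night screening.
#' @param screen_blackout blackout-screen position, %.
#' @param hd_sp humidity-deficit setpoint, g/m3.
#' @param co2_sp CO2 concentration setpoint, ppm (300-1200).
#' @param co2_capacity CO2 dosing capacity, kg/ha/h.
#' @param co2_taper_week season week after which the CO2 setpoint declines
#'   linearly towards `co2_sp_end` (ventilation makes summer dosing futile).
#' @param co2_sp_end ppm setpoint reached in the final season week.
#' @param irrigation_interval minutes between irrigation turns.
#' @param supply_ec irrigation supply EC, dS/m.
#' @param drain_target seasonal drain fraction aimed for by fertigation (0-1).
#' @return a `ghw_schedule` object.
#' @export
new_schedule <- function(season_start = as.Date("2019-12-16"),
                         season_end = as.Date("2020-05-29"),
                         weekly_hours = 12,
                         led_on = TRUE,
                         led_channels = c(blue = 100, red = 100, farred = 100, white = 100),
                         t_day = 22, t_night = 20, vent_offset = 1.5,
                         min_rail_pipe = 0, min_crop_pipe = 0,
                         min_vent_opening = 0,
                         screen_energy_night = 95, screen_weeks = 16,
                         screen_blackout = 0,
                         hd_sp = 2.5,
                         co2_sp = 800, co2_capacity = 120,
                         co2_taper_week = 13, co2_sp_end = 450,
                         irrigation_interval = 180,
                         supply_ec = 3.2, drain_target = 0.32) {
  season_start <- as.Date(season_start); season_end <- as.Date(season_end)
  nw <- n_season_weeks(season_start, season_end)
  if (length(weekly_hours) == 1) weekly_hours <- rep(weekly_hours, nw)
  if (length(weekly_hours) != nw)
    stopf("weekly_hours has length %d; season has %d weeks", length(weekly_hours), nw)
  s <- list(season_start = season_start, season_end = season_end,
            weekly_hours = as.numeric(weekly_hours),
            led_on = isTRUE(led_on), led_channels = led_channels,
            t_day = t_day, t_night = t_night, vent_offset = vent_offset,
            min_rail_pipe = min_rail_pipe, min_crop_pipe = min_crop_pipe,
            min_vent_opening = min_vent_opening,
            screen_energy_night = screen_energy_night, screen_weeks = screen_weeks,
            screen_blackout = screen_blackout,
            hd_sp = hd_sp, co2_sp = co2_sp, co2_capacity = co2_capacity,
            co2_taper_week = co2_taper_week, co2_sp_end = co2_sp_end,
            irrigation_interval = irrigation_interval,
            supply_ec = supply_ec, drain_target = drain_target,
            temp_shift_applied = 0, light_delta_applied = 0)
  class(s) <- "ghw_schedule"
  s
}

#' Construct a crop-management plan
#'
#' @param planting_date,topping_date,last_harvest_date crop calendar (`Date`);
#'   must be strictly increasing.
#' @param initial_stem_density stems/m2 at planting (2.6-4.0 in the challenge).
#' @param stem_density_changes data.frame with columns `date`, `stems` giving
#'   dated increases of stem density (side shoots released), or `NULL`.
#' @param fruits_per_truss_target fruits kept per truss after pruning.
#' @param truss_type `"single"` or `"split"`; caps pruning at 16 resp. 20.
#' @param plants_are_two_stem young plants bought as 2-stem (affects plant cost).
#' @return a `ghw_plan` object.
#' @export
new_plan <- function(planting_date = as.Date("2019-12-16"),
                     initial_stem_density = 3.0,
                     stem_density_changes = NULL,
                     fruits_per_truss_target = 13,
                     truss_type = c("single", "split"),
                     topping_date = as.Date("2020-04-20"),
                     last_harvest_date = as.Date("2020-05-29"),
                     plants_are_two_stem = TRUE) {
  truss_type <- match.arg(truss_type)
  if (is.null(stem_density_changes))
    stem_density_changes <- data.frame(date = as.Date(character()), stems = numeric())
  stem_density_changes$date <- as.Date(stem_density_changes$date)
  p <- list(planting_date = as.Date(planting_date),
            initial_stem_density = initial_stem_density,
            stem_density_changes = stem_density_changes,
            fruits_per_truss_target = fruits_per_truss_target,
            truss_type = truss_type,
            topping_date = as.Date(topping_date),
            last_harvest_date = as.Date(last_harvest_date),
            plants_are_two_stem = isTRUE(plants_are_two_stem))
  class(p) <- "ghw_plan"
  p
}

max_fruits_per_truss <- function(truss_type) if (truss_type == "split") 20L else 16L

#' Expand a schedule to 5-minute slots
#'
#' @param schedule a `ghw_schedule`.
#' @param timestamps POSIXct at 5-min spacing; defaults to the schedule's
#'   full season.
#' @param latitude degrees north, for the solar clock.
#' @return a data.frame, one row per slot, with the actuator setpoints
#'   (`hps_on`, `led_on`, `heat_sp`, `vent_temp`, `min_vent`, `screen_energy`,
#'   `screen_blackout`, `hd_sp`, `co2_sp`, `co2_capacity` (g/m2/h),
#'   `min_rail_pipe`, `min_crop_pipe`, `irrigation_interval`).
#' @export
expand_schedule <- function(schedule, timestamps = NULL, latitude = 52.0) {
  if (is.null(timestamps)) {
    t0 <- as.POSIXct(paste(schedule$season_start, "00:00:00"), tz = "UTC")
    t1 <- as.POSIXct(paste(schedule$season_end, "23:55:00"), tz = "UTC")
    timestamps <- seq(t0, t1, by = 300)
  }
  hod <- as.numeric(timestamps - trunc(timestamps, "days"), units = "hours")
  wk <- season_week(timestamps, schedule$season_start)
  wk <- pmin(wk, length(schedule$weekly_hours))
  hrs <- schedule$weekly_hours[wk]
  hps_on <- hod >= (12 - hrs / 2) & hod < (12 + hrs / 2)
  led_on <- hps_on & schedule$led_on
  elev <- solar_elevation(timestamps, latitude)
  is_day <- hps_on | elev > 0
  screen <- ifelse(!is_day & wk <= schedule$screen_weeks,
                   schedule$screen_energy_night, 0)
  nw <- length(schedule$weekly_hours)
  co2_sp <- ifelse(wk <= schedule$co2_taper_week, schedule$co2_sp,
                   schedule$co2_sp + (schedule$co2_sp_end - schedule$co2_sp) *
                     (wk - schedule$co2_taper_week) /
                     max(1, nw - schedule$co2_taper_week))
  data.frame(
    timestamp = timestamps,
    hps_on = hps_on, led_on = led_on,
    heat_sp = ifelse(is_day, schedule$t_day, schedule$t_night),
    vent_temp = ifelse(is_day, schedule$t_day, schedule$t_night) + schedule$vent_offset,
    min_vent = schedule$min_vent_opening,
    screen_energy = screen,
    screen_blackout = schedule$screen_blackout,
    hd_sp = schedule$hd_sp,
    co2_sp = co2_sp,
    co2_capacity = schedule$co2_capacity * 0.1,   # kg/ha/h -> g/m2/h
    min_rail_pipe = schedule$min_rail_pipe,
    min_crop_pipe = schedule$min_crop_pipe,
    irrigation_interval = schedule$irrigation_interval
  )
}

#' Six archetype strategy presets (compartments 301-306)
#'
#' Returns a schedule/plan pair emulating the control archetype of one of the
#' six greenhouse compartments: 301 runs very high CO2 dosing with the latest
#' topping date, 302 a low-light low-cost strategy, 303 (the manually grown
#' reference) relatively high temperatures with a stem-density doubling to
#' 8.0 stems/m2 just before topping, 304 low artificial light with a high
#' fruit load, 305 the heaviest supplemental-lighting share, and 306 high
#' temperatures with a balanced plant load. Topping dates are the exact
#' per-compartment calendar; quantitative setpoint levels are calibrated
#' archetypes, not reconstructions (see `preset-calibration` in inst/extdata).
#'
#' @param compartment_id integer in 301..306.
#' @return a `ghw_preset` list with elements `compartment`, `schedule`,
#'   `plan`, `brix_modifier` (degBrix strategy offset used by [assign_brix()]).
#' @examples
#' p <- make_preset(303)
#' p$plan$topping_date
#' @export
make_preset <- function(compartment_id) {
  id <- as.integer(compartment_id)
  if (!id %in% 301:306) stopf("unknown compartment id %s (expected 301..306)", compartment_id)
  wkprof <- function(pts) stats::approx(c(1, 8, 14, 19, 24), pts, xout = 1:24)$y
  cfg <- switch(as.character(id),
    "301" = list(hours = c(15.5, 15.5, 12.5, 8, 4), t_day = 21.7, t_night = 20.2,
                 co2_sp = 900, co2_cap = 110, topping = "2020-04-30",
                 init = 3.8, chg = data.frame(date = as.Date("2020-03-01"), stems = 5.0),
                 fpt = 15, ec = 3.01, drain = 0.32, brix = 0.05),
    "302" = list(hours = c(15.25, 15.25, 11.75, 8, 3.5), t_day = 22.7, t_night = 21.2,
                 co2_sp = 900, co2_cap = 100, topping = "2020-04-16",
                 init = 2.6, chg = data.frame(date = as.Date(c("2020-01-25", "2020-03-01")),
                                              stems = c(3.8, 5.3)),
                 fpt = 16, ec = 3.21, drain = 0.37, brix = 0.15),
    "303" = list(hours = c(15.5, 15.5, 12, 8, 4), t_day = 23.35, t_night = 21.85,
                 co2_sp = 750, co2_cap = 60, topping = "2020-04-17",
                 init = 4.0, chg = data.frame(date = as.Date(c("2020-02-15", "2020-04-03")),
                                              stems = c(4.4, 8.0)),
                 fpt = 14, ec = 3.61, drain = 0.35, brix = -0.05),
    "304" = list(hours = c(15, 15, 11.5, 7.5, 3.5), t_day = 21.85, t_night = 20.35,
                 co2_sp = 850, co2_cap = 70, topping = "2020-04-23",
                 init = 3.4, chg = data.frame(date = as.Date(c("2020-02-01", "2020-03-15")),
                                              stems = c(4.4, 5.0)),
                 fpt = 16, ec = 3.35, drain = 0.355, brix = 0.0),
    "305" = list(hours = c(16.5, 16.5, 13.5, 9.5, 5), t_day = 21.6, t_night = 20.1,
                 co2_sp = 650, co2_cap = 75, topping = "2020-04-24",
                 init = 3.0, chg = data.frame(date = as.Date(c("2020-02-05", "2020-03-15")),
                                              stems = c(3.9, 4.6)),
                 fpt = 17, ec = 3.58, split = TRUE, drain = 0.33, brix = 0.45),
    "306" = list(hours = c(15.5, 15.5, 12.5, 8, 4), t_day = 23.95, t_night = 22.55,
                 co2_sp = 800, co2_cap = 75, topping = "2020-04-21",
                 init = 3.0, chg = data.frame(date = as.Date(c("2020-01-20", "2020-03-15")),
                                              stems = c(4.2, 5.85)),
                 fpt = 14, ec = 3.32, drain = 0.30, brix = 0.15))
  schedule <- new_schedule(weekly_hours = wkprof(cfg$hours),
                           t_day = cfg$t_day, t_night = cfg$t_night,
                           co2_sp = cfg$co2_sp, co2_capacity = cfg$co2_cap,
                           supply_ec = cfg$ec, drain_target = cfg$drain)
  plan <- new_plan(initial_stem_density = cfg$init,
                   stem_density_changes = cfg$chg,
                   fruits_per_truss_target = cfg$fpt,
                   truss_type = if (isTRUE(cfg$split)) "split" else "single",
                   topping_date = as.Date(cfg$topping))
  structure(list(compartment = id, schedule = schedule, plan = plan,
                 brix_modifier = cfg$brix),
            class = "ghw_preset")
}

#' Validate a schedule and crop plan
#'
#' Checks every declared invariant and returns a data.frame of violations
#' (possibly zero rows); it never throws. Slot-level checks accept either a
#' `ghw_schedule` (expanded internally) or an already-expanded slot table so
#' that externally perturbed slot tables can be audited too.
#'
#' @param schedule `ghw_schedule` or a slot data.frame from [expand_schedule()].
#' @param plan a `ghw_plan`, or `NULL` to validate the schedule alone.
#' @return data.frame with columns `field`, `slot`, `rule`.
#' @export
validate_strategy <- function(schedule, plan = NULL) {
  v <- list()
  add <- function(field, slot, rule)
    v[[length(v) + 1]] <<- data.frame(field = field, slot = slot, rule = rule)

  slots <- if (inherits(schedule, "ghw_schedule")) expand_schedule(schedule) else schedule
  bad <- which(slots$led_on & !slots$hps_on)
  for (i in head(bad, 50)) add("led_on", i, "LED power is coupled to HPS: led_on requires hps_on")
  pct_fields <- c("min_vent", "screen_energy", "screen_blackout")
  for (f in pct_fields) {
    bad <- which(slots[[f]] < 0 | slots[[f]] > 100)
    for (i in head(bad, 50)) add(f, i, "percentage outside [0, 100]")
  }
  bad <- which(slots$co2_sp < 300 | slots$co2_sp > 1200)
  for (i in head(bad, 50)) add("co2_sp", i, "CO2 setpoint outside [300, 1200] ppm")
  bad <- which(slots$irrigation_interval <= 0)
  for (i in head(bad, 50)) add("irrigation_interval", i, "irrigation interval must be positive")
  if (inherits(schedule, "ghw_schedule")) {
    ch <- schedule$led_channels
    if (any(ch < 0 | ch > 100)) add("led_channels", NA, "LED channel intensity outside [0, 100] %")
  }

  if (!is.null(plan)) {
    dens <- c(plan$initial_stem_density, plan$stem_density_changes$stems)
    if (any(dens < 2.6 | dens > 8.0))
      add("stem_density", NA, "stem density outside the 2.6-8.0 stems/m2 envelope")
    cap <- max_fruits_per_truss(plan$truss_type)
    if (plan$fruits_per_truss_target > cap)
      add("fruits_per_truss_target", NA,
          sprintf("target exceeds %d-fruit cap for %s trusses", cap, plan$truss_type))
    if (!(plan$planting_date < plan$topping_date &&
          plan$topping_date < plan$last_harvest_date))
      add("calendar", NA, "require planting_date < topping_date < last_harvest_date")
  }
  if (length(v) == 0)
    data.frame(field = character(), slot = integer(), rule = character())
  else do.call(rbind, v)
}

#' Perturbation operators on schedules
#'
#' The sensitivity operators of the performance analysis. Each one is the
#' identity at zero perturbation and touches only the fields it names.
#' `shift_temperature` moves the heating line (and with it the ventilation
#' line) and both minimum-pipe setpoints by `delta`; the +/-2 degC bound is
#' cumulative over repeated calls. `adjust_lighting_hours` lengthens or
#' shortens every day's lamp block symmetrically around its solar-noon
#' midpoint by `delta_hours_per_day` (cumulative bound +/-3 h, result clamped
#' to [0, 24] h with a warning). `adjust_co2` shifts the CO2 setpoint and
#' replaces the dosing capacity. `set_weekly_lighting_hours` overrides the
#' per-week photoperiod profile wholesale.
#'
#' @param schedule a `ghw_schedule`.
#' @param delta temperature shift, degC, cumulative |delta| <= 2.
#' @param delta_hours_per_day lighting-hours change, h, cumulative |delta| <= 3.
#' @param sp_offset CO2 setpoint offset, ppm, in [-100, +50].
#' @param capacity CO2 dosing capacity, kg/ha/h, in [50, 200].
#' @param hours_by_week numeric vector, h/day per season week, each in [0, 20].
#' @return the modified `ghw_schedule`.
#' @export
shift_temperature <- function(schedule, delta) {
  total <- schedule$temp_shift_applied + delta
  if (abs(total) > 2 + 1e-9)
    stopf("cumulative temperature shift %.2f degC outside [-2, +2]", total)
  schedule$t_day <- schedule$t_day + delta
  schedule$t_night <- schedule$t_night + delta
  schedule$min_rail_pipe <- schedule$min_rail_pipe + delta
  schedule$min_crop_pipe <- schedule$min_crop_pipe + delta
  schedule$temp_shift_applied <- total
  schedule
}

#' @rdname shift_temperature
#' @export
adjust_lighting_hours <- function(schedule, delta_hours_per_day) {
  total <- schedule$light_delta_applied + delta_hours_per_day
  if (abs(total) > 3 + 1e-9)
    stopf("cumulative lighting-hours change %.2f h outside [-3, +3]", total)
  h <- schedule$weekly_hours + delta_hours_per_day
  if (any(h < 0 | h > 24)) {
    warnf("lighting hours clamped to [0, 24] h/day in %d week(s)", sum(h < 0 | h > 24))
    h <- clamp(h, 0, 24)
  }
  schedule$weekly_hours <- h
  schedule$light_delta_applied <- total
  schedule
}

#' @rdname shift_temperature
#' @export
adjust_co2 <- function(schedule, sp_offset = 0, capacity = schedule$co2_capacity) {
  if (sp_offset < -100 || sp_offset > 50)
    stopf("CO2 setpoint offset %.0f ppm outside [-100, +50]", sp_offset)
  if (capacity < 50 || capacity > 200)
    stopf("CO2 dosing capacity %.0f kg/ha/h outside [50, 200]", capacity)
  schedule$co2_sp <- schedule$co2_sp + sp_offset
  schedule$co2_sp_end <- schedule$co2_sp_end + sp_offset
  schedule$co2_capacity <- capacity
  schedule
}

#' @rdname shift_temperature
#' @export
set_weekly_lighting_hours <- function(schedule, hours_by_week) {
  nw <- length(schedule$weekly_hours)
  if (length(hours_by_week) != nw)
    stopf("hours_by_week has length %d; season has %d weeks", length(hours_by_week), nw)
  if (any(hours_by_week < 0 | hours_by_week > 20))
    stopf("weekly lighting hours must lie in [0, 20] h/day")
  schedule$weekly_hours <- as.numeric(hours_by_week)
  schedule
}

# ---- plain-text strategy config (INI-style, lossless round-trip) ----------

fmt_val <- function(x) {
  if (inherits(x, "Date")) return(format(x, "%Y-%m-%d"))
  if (is.logical(x)) return(ifelse(x, "true", "false"))
  if (is.numeric(x)) return(paste(format(x, digits = 17, scientific = FALSE, trim = TRUE),
                                  collapse = ","))
  paste(as.character(x), collapse = ",")
}

#' Save / load a strategy as a plain-text config
#'
#' Sections `[schedule]` and `[plan]` with `key = value` lines; vectors are
#' comma-separated, stem-density changes `date:stems` pairs separated by `;`.
#' `load -> save -> load` round-trips losslessly.
#'
#' @param preset a `ghw_preset` (or a list with `schedule` and `plan`).
#' @param path file path.
#' @return `read_strategy` returns a `ghw_preset`.
#' @export
write_strategy <- function(preset, path) {
  s <- preset$schedule; p <- preset$plan
  ln <- c("[meta]",
          sprintf("compartment = %s", preset$compartment %||% 0),
          sprintf("brix_modifier = %s", fmt_val(preset$brix_modifier %||% 0)),
          "[schedule]")
  skip <- c("temp_shift_applied", "light_delta_applied")
  for (k in setdiff(names(s), skip)) {
    if (k == "led_channels")
      ln <- c(ln, sprintf("led_channels = %s",
                          paste(vapply(seq_along(s$led_channels), function(j)
                            sprintf("%s:%s", names(s$led_channels)[j],
                                    fmt_val(unname(s$led_channels[j]))), ""),
                            collapse = ";")))
    else ln <- c(ln, sprintf("%s = %s", k, fmt_val(s[[k]])))
  }
  ln <- c(ln, "[plan]")
  for (k in names(p)) {
    if (k == "stem_density_changes") {
      ch <- p$stem_density_changes
      val <- if (nrow(ch) == 0) "" else
        paste(vapply(seq_len(nrow(ch)), function(j)
          sprintf("%s:%s", format(ch$date[j], "%Y-%m-%d"), fmt_val(ch$stems[j])), ""),
          collapse = ";")
      ln <- c(ln, sprintf("stem_density_changes = %s", val))
    } else ln <- c(ln, sprintf("%s = %s", k, fmt_val(p[[k]])))
  }
  writeLines(ln, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname write_strategy
#' @export
read_strategy <- function(path) {
  ln <- trimws(readLines(path))
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  section <- ""
  kv <- list(meta = list(), schedule = list(), plan = list())
  for (l in ln) {
    if (startsWith(l, "[")) { section <- gsub("\\[|\\]", "", l); next }
    eq <- regexpr("=", l, fixed = TRUE)
    k <- trimws(substr(l, 1, eq - 1)); val <- trimws(substr(l, eq + 1, nchar(l)))
    kv[[section]][[k]] <- val
  }
  parse_num <- function(x) as.numeric(strsplit(x, ",", fixed = TRUE)[[1]])
  sch <- kv$schedule
  led <- strsplit(sch$led_channels, ";", fixed = TRUE)[[1]]
  led_v <- vapply(strsplit(led, ":", fixed = TRUE), function(z) as.numeric(z[2]), 0)
  names(led_v) <- vapply(strsplit(led, ":", fixed = TRUE), `[`, "", 1)
  schedule <- new_schedule(
    season_start = as.Date(sch$season_start), season_end = as.Date(sch$season_end),
    weekly_hours = parse_num(sch$weekly_hours),
    led_on = identical(sch$led_on, "true"), led_channels = led_v,
    t_day = parse_num(sch$t_day), t_night = parse_num(sch$t_night),
    vent_offset = parse_num(sch$vent_offset),
    min_rail_pipe = parse_num(sch$min_rail_pipe),
    min_crop_pipe = parse_num(sch$min_crop_pipe),
    min_vent_opening = parse_num(sch$min_vent_opening),
    screen_energy_night = parse_num(sch$screen_energy_night),
    screen_weeks = parse_num(sch$screen_weeks),
    screen_blackout = parse_num(sch$screen_blackout),
    hd_sp = parse_num(sch$hd_sp),
    co2_sp = parse_num(sch$co2_sp), co2_capacity = parse_num(sch$co2_capacity),
    co2_taper_week = parse_num(sch$co2_taper_week),
    co2_sp_end = parse_num(sch$co2_sp_end),
    irrigation_interval = parse_num(sch$irrigation_interval),
    supply_ec = parse_num(sch$supply_ec), drain_target = parse_num(sch$drain_target))
  pl <- kv$plan
  chg <- NULL
  if (nzchar(pl$stem_density_changes %||% "")) {
    parts <- strsplit(strsplit(pl$stem_density_changes, ";", fixed = TRUE)[[1]],
                      ":", fixed = TRUE)
    chg <- data.frame(date = as.Date(vapply(parts, `[`, "", 1)),
                      stems = as.numeric(vapply(parts, `[`, "", 2)))
  }
  plan <- new_plan(planting_date = as.Date(pl$planting_date),
                   initial_stem_density = parse_num(pl$initial_stem_density),
                   stem_density_changes = chg,
                   fruits_per_truss_target = parse_num(pl$fruits_per_truss_target),
                   truss_type = pl$truss_type,
                   topping_date = as.Date(pl$topping_date),
                   last_harvest_date = as.Date(pl$last_harvest_date),
                   plants_are_two_stem = identical(pl$plants_are_two_stem, "true"))
  structure(list(compartment = as.integer(kv$meta$compartment %||% 0L),
                 schedule = schedule, plan = plan,
                 brix_modifier = as.numeric(kv$meta$brix_modifier %||% 0)),
            class = "ghw_preset")
}
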