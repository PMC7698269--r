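# Shared fixtures: short seasons keep module tests fast; the full six-preset
# season runs live in test-acceptance.R only.

short_weather <- function(seed = 1, start = "2019-12-16", end = "2020-01-05") {
  generate_weather(start, end, seed = seed)
}

# A truncated 306-style preset: ~14-week season, early topping, so that a
# full run (including harvests) takes well under a second.
short_preset <- function(compartment = 306, season_end = "2020-03-20",
                         topping = "2020-02-05") {
  pr <- make_preset(compartment)
  nw <- n_weeks_between(pr$schedule$season_start, as.Date(season_end))
  pr$schedule$season_end <- as.Date(season_end)
  pr$schedule$weekly_hours <- pr$schedule$weekly_hours[seq_len(nw)]
  pr$plan$topping_date <- as.Date(topping)
  pr$plan$last_harvest_date <- as.Date(season_end)
  pr$plan$stem_density_changes <-
    pr$plan$stem_density_changes[pr$plan$stem_density_changes$date <= as.Date(season_end), ,
                                 drop = FALSE]
  pr
}

n_weeks_between <- function(a, b) as.integer(ceiling((as.numeric(b - a) + 1) / 7))

# passive schedule: no heating, no lamps, no screens, vents fixed half open
passive_schedule <- function(season_start, season_end) {
  new_schedule(season_start = season_start, season_end = season_end,
               weekly_hours = 0, t_day = -50, t_night = -50, vent_offset = 0,
               min_rail_pipe = 0, min_crop_pipe = 0, min_vent_opening = 50,
               screen_energy_night = 0, screen_weeks = 0, co2_capacity = 50)
}

# constant-climate crop run: drives the crop model alone at a fixed daily
# mean temperature and daily assimilation, returning state + harvest log
run_crop_const <- function(t_mean, gross, plan, params = crop_params(), n_days = NULL) {
  dates <- seq(plan$planting_date, plan$last_harvest_date, by = "day")
  if (!is.null(n_days)) dates <- dates[seq_len(n_days)]
  st <- new_crop_state(plan, params)
  harvests <- list(); loads <- numeric(length(dates))
  for (i in seq_along(dates)) {
    st <- apply_crop_actions(st, plan, dates[i])
    dh <- develop_and_harvest(st, t_mean, dates[i], plan, params)
    st <- dh$state
    if (nrow(dh$harvests) > 0) harvests[[length(harvests) + 1]] <- dh$harvests
    st <- daily_carbon_update(st, gross, t_mean, params)
    loads[i] <- plant_load(st)
  }
  list(state = st, loads = loads, dates = dates,
       harvests = if (length(harvests)) do.call(rbind, harvests) else
         data.frame(date = as.Date(character()), trusses_harvested = numeric(),
                    fresh_weight = numeric(), mean_fruit_weight = numeric(),
                    fruit_growth_period = numeric()))
}

season_week_of <- function(ts, start)
  pmax(1L, 1L + (as.integer(as.Date(ts) - start) %/% 7L))
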