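#' Run configuration
#'
#' @param preset compartment id (301-306) or a `ghw_preset` object.
#' @param seed integer master seed; the weather stream and the Brix noise
#'   stream are derived from it, so a run is reproducible from `(preset, seed)`
#'   plus parameter overrides.
#' @param weather optional pre-generated `ghw_weather` (seed then only feeds
#'   the Brix noise).
#' @param params,crop,quality,prices,tf parameter objects; defaults used when
#'   `NULL` (quality defaults to the preset's strategy modifier).
#' @param out_dir optional directory; when set, [run_season()] writes climate,
#'   crop and harvest CSVs plus a reproducibility manifest there.
#' @param verbose narrate season milestones.
#' @return a `ghw_config` list.
#' @export
run_config <- function(preset = 306, seed = 1L, weather = NULL,
                       params = NULL, crop = NULL, quality = NULL,
                       prices = NULL, tf = NULL, out_dir = NULL,
                       verbose = FALSE) {
  if (!inherits(preset, "ghw_preset")) preset <- make_preset(preset)
  structure(list(preset = preset, seed = as.integer(seed), weather = weather,
                 params = params %||% greenhouse_params(),
                 crop = crop %||% crop_params(),
                 quality = quality %||% quality_params(strategy_modifier = preset$brix_modifier),
                 prices = prices %||% price_model(),
                 tf = tf %||% tariffs(),
                 out_dir = out_dir, verbose = isTRUE(verbose)),
            class = "ghw_config")
}

#' Simulate one full season
#'
#' The coupled climate-crop co-simulation: the compiled 5-minute climate
#' kernel advances one day at a time with the crop's leaf area index and dark
#' respiration held at the previous day's value (explicit co-simulation with
#' a one-day lag on the slow crop variables), then the crop model consumes
#' the day's summed hourly photosynthesis, initiates and ages trusses,
#' partitions carbohydrates and harvests ripe trusses. Afterwards Brix is
#' assigned to every harvest record and the season is scored at the
#' published tariffs. Fully deterministic given the config: all randomness
#' comes from the weather seed and the Brix noise seed derived from
#' `config$seed`.
#'
#' @param config a `ghw_config` from [run_config()].
#' @return a `ghw_season` list: `climate` (5-min), `daily` (climate + carbon
#'   ledger), `crop_daily` (LAI, plant load, stems, trusses/stem, cumulative
#'   yield), `harvests`, `ledger`, `economics`, `weather`, `manifest`.
#' @examples
#' \donttest{
#' res <- run_season(run_config(306, seed = 1))
#' res$economics
#' }
#' @export
run_season <- function(config = run_config()) {
  stopifnot(inherits(config, "ghw_config"))
  preset <- config$preset
  schedule <- preset$schedule; plan <- preset$plan
  viol <- validate_strategy(schedule, plan)
  if (nrow(viol) > 0)
    stopf("invalid strategy: %s", paste(unique(viol$rule), collapse = "; "))

  weather <- config$weather %||%
    generate_weather(schedule$season_start, schedule$season_end,
                     seed = config$seed)
  slots <- expand_schedule(schedule, timestamps = weather$timestamp)
  n <- nrow(weather)
  dates <- as.Date(weather$timestamp)
  udays <- unique(dates)
  day_idx <- match(dates, udays)
  hod <- as.numeric(weather$timestamp - trunc(weather$timestamp, "days"), units = "hours")
  ah_out <- sat_abs_humidity(weather$temp_out) * weather$rh_out / 100

  params <- config$params; crop <- config$crop
  pars <- params; pars$crop <- crop
  state <- c(weather$temp_out[1] + 2, params$co2_outside,
             0.8 * sat_abs_humidity(weather$temp_out[1] + 2))
  cs <- new_crop_state(plan, crop)

  nd <- length(udays)
  cols <- c("temp_in", "co2_in", "ah_in", "par_in", "vent_opening", "heat_power",
            "lamp_elec", "co2_dose", "assim", "transp")
  acc <- matrix(NA_real_, n, length(cols), dimnames = list(NULL, cols))
  daily <- data.frame(date = udays, heat_J = 0, elec_peak_J = 0, elec_off_J = 0,
                      co2_g = 0, co2_uptake_g = 0, co2_vent_g = 0, transp_g = 0,
                      fog_g = 0, assim_ch2o_g = 0, temp_mean = NA_real_,
                      par_mol = NA_real_, lai = NA_real_,
                      respiration = NA_real_, growth_ch2o = NA_real_,
                      discard = NA_real_)
  crop_daily <- data.frame(date = udays, lai = NA_real_, stems = NA_real_,
                           plant_load = NA_real_, trusses_per_stem = NA_real_,
                           veg_biomass = NA_real_, fruit_biomass = NA_real_,
                           cum_yield = NA_real_)
  harvest_list <- list()
  say <- function(...) if (config$verbose) message(sprintf(...))
  milestones <- c(first_truss = FALSE, first_harvest = FALSE, topping = FALSE)

  for (d in seq_len(nd)) {
    date <- udays[d]
    ii <- which(day_idx == d)
    rd <- dark_respiration_co2(cs, 20, crop)
    r <- .climate_day_cpp(weather$global_radiation[ii], weather$par_outside[ii],
                          weather$temp_out[ii], ah_out[ii], weather$wind[ii],
                          slots$hps_on[ii], slots$led_on[ii],
                          slots$heat_sp[ii], slots$vent_temp[ii], slots$min_vent[ii],
                          slots$screen_energy[ii], slots$screen_blackout[ii],
                          slots$co2_sp[ii], slots$co2_capacity[ii], slots$hd_sp[ii],
                          slots$min_rail_pipe[ii], slots$min_crop_pipe[ii],
                          hod[ii], state[1], state[2], state[3],
                          cs$lai, rd, pars, 300)
    for (cn in cols) acc[ii, cn] <- r[[cn]]
    state <- r$state
    t_mean <- mean(r$temp_in)

    cs <- apply_crop_actions(cs, plan, date)
    dh <- develop_and_harvest(cs, t_mean, date, plan, crop)
    cs <- dh$state
    if (nrow(dh$harvests) > 0) {
      harvest_list[[length(harvest_list) + 1]] <- dh$harvests
      if (!milestones["first_harvest"]) {
        say("first harvest on %s", date); milestones["first_harvest"] <- TRUE
      }
    }
    cs <- daily_carbon_update(cs, r$assim_ch2o_g, t_mean, crop)
    carbon <- attr(cs, "carbon")

    daily$heat_J[d] <- r$heat_J; daily$elec_peak_J[d] <- r$elec_peak_J
    daily$elec_off_J[d] <- r$elec_off_J; daily$co2_g[d] <- r$co2_g
    daily$co2_uptake_g[d] <- r$co2_uptake_g; daily$co2_vent_g[d] <- r$co2_vent_g
    daily$transp_g[d] <- r$transp_g; daily$fog_g[d] <- r$fog_g
    daily$assim_ch2o_g[d] <- r$assim_ch2o_g
    daily$temp_mean[d] <- t_mean
    daily$par_mol[d] <- sum(r$par_in) * 300 / 1e6
    daily$lai[d] <- cs$lai
    daily$respiration[d] <- carbon["respiration"]
    daily$growth_ch2o[d] <- carbon["growth_ch2o"]
    daily$discard[d] <- carbon["discard"]

    crop_daily$lai[d] <- cs$lai
    crop_daily$stems[d] <- sum(cs$cohorts$stems)
    crop_daily$plant_load[d] <- plant_load(cs)
    # per-stem count of the original planting cohort (what staff counted)
    crop_daily$trusses_per_stem[d] <- cs$cohorts$cum_trusses[1]
    crop_daily$veg_biomass[d] <- cs$veg_biomass
    crop_daily$fruit_biomass[d] <- cs$fruit_biomass
    crop_daily$cum_yield[d] <- cs$cum_yield_kg

    if (!milestones["first_truss"] && nrow(cs$trusses) > 0) {
      say("first truss initiated on %s", date); milestones["first_truss"] <- TRUE
    }
    if (!milestones["topping"] && date >= plan$topping_date) {
      say("crop topped on %s", plan$topping_date); milestones["topping"] <- TRUE
    }
  }
  say("final harvest day %s; cumulative yield %.2f kg/m2",
      plan$last_harvest_date, cs$cum_yield_kg)

  harvests <- if (length(harvest_list) > 0) do.call(rbind, harvest_list) else
    data.frame(date = as.Date(character()), trusses_harvested = numeric(),
               fresh_weight = numeric(), mean_fruit_weight = numeric(),
               fruit_growth_period = numeric())
  harvests <- assign_brix(harvests, config$quality, crop$dm_fraction,
                          seed = config$seed + 1000L)

  climate <- data.frame(timestamp = weather$timestamp, acc)
  ledger <- resource_ledger(daily, schedule)
  stem_days <- sum(crop_daily$stems)
  econ <- economic_result(harvests, ledger, plan, stem_days,
                          config$prices, config$tf)

  manifest <- list(package_version = as.character(utils::packageVersion("tomatotwin")),
                   compartment = preset$compartment,
                   seed = config$seed,
                   weather_seed = attr(weather, "seed") %||% NA,
                   config_hash = config_hash(config),
                   season = c(format(schedule$season_start), format(schedule$season_end)))

  res <- structure(list(compartment = preset$compartment, config = config,
                        weather = weather, climate = climate, daily = daily,
                        crop_daily = crop_daily, harvests = harvests,
                        ledger = ledger, economics = econ,
                        crop_state = cs, manifest = manifest),
                   class = "ghw_season")
  if (!is.null(config$out_dir)) write_season_outputs(res, config$out_dir)
  res
}

# rolling polynomial hash over the serialized config (manifest only; base R)
config_hash <- function(config) {
  cfg <- config[setdiff(names(config), c("weather", "out_dir", "verbose"))]
  raw <- as.integer(serialize(cfg, NULL, version = 2))
  h <- 0
  for (b in raw) h <- (h * 257 + b + 1) %% 2147483647
  sprintf("%08x", h)
}

#' Write season outputs to a directory
#'
#' Daily climate aggregates, daily crop state, harvest records (CSV) and a
#' JSON manifest (package version, seeds, config hash) sufficient to
#' reproduce the run exactly.
#'
#' @param result a `ghw_season`.
#' @param dir output directory (created if needed).
#' @export
write_season_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_daily_climate_csv(result$daily, result$config$preset$schedule,
                          file.path(dir, "climate_daily.csv"))
  write.csv(result$crop_daily, file.path(dir, "crop_daily.csv"), row.names = FALSE)
  write.csv(result$harvests, file.path(dir, "harvests.csv"), row.names = FALSE)
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @export
print.ghw_season <- function(x, ...) {
  cat(sprintf("Season run, compartment %d (seed %d): yield %.2f kg/m2 over %d harvest days\n",
              x$compartment, x$config$seed, x$economics$yield,
              length(unique(x$harvests$date))))
  print(x$economics)
  invisible(x)
}

#' Compare preset runs
#'
#' @param results list of at least two `ghw_season` objects.
#' @return data.frame, one row per run, sorted by net profit (descending),
#'   with income, cost components, net profit and resource-use efficiencies;
#'   `net_profit = income - costs_total` holds exactly per row.
#' @export
compare_presets <- function(results) {
  if (length(results) < 2) stopf("need at least two season runs to compare")
  rows <- lapply(results, function(r) {
    e <- r$economics
    data.frame(compartment = r$compartment, yield = e$yield,
               income = e$income, costs_total = e$costs$total,
               net_profit = e$net_profit,
               plants = e$costs$plants,
               electricity = e$costs$electricity_peak + e$costs$electricity_offpeak,
               heat = e$costs$heat, co2 = e$costs$co2, labor = e$costs$labor,
               rue_heat = e$rue["heat"], rue_electricity = e$rue["electricity"],
               rue_co2 = e$rue["co2"], rue_water = e$rue["water"],
               rue_nutrients = e$rue["nutrients"], row.names = NULL)
  })
  tab <- do.call(rbind, rows)
  tab[order(-tab$net_profit), , drop = FALSE]
}
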