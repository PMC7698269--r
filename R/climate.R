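#' PAR at crop level
#'
#' Transmitted sunlight plus lamp PAR: cover transmissivity and screen
#' shading applied to outside PAR, then HPS capacity and the LED channels
#' excluding the far-red channel (far-red photons are not PAR).
#'
#' @param par_outside umol/m2/s outside.
#' @param hps_on,led_on logical lamp states.
#' @param screen_energy,screen_blackout screen positions, %.
#' @param params [greenhouse_params()].
#' @param led_channels LED channel intensities, % of channel capacity.
#' @return PAR at crop level, umol/m2/s.
#' @examples
#' par_inside(0, hps_on = TRUE, led_on = TRUE)   # 197: 100 HPS + 97 LED PAR
#' @export
par_inside <- function(par_outside, hps_on = FALSE, led_on = FALSE,
                       screen_energy = 0, screen_blackout = 0,
                       params = greenhouse_params(),
                       led_channels = c(blue = 100, red = 100, farred = 100, white = 100)) {
  if (any(par_outside < 0)) stopf("par_outside must be non-negative")
  scr <- (1 - params$screen_energy_shading * screen_energy / 100) *
    (1 - params$screen_blackout_shading * screen_blackout / 100)
  caps <- params$led_channel_caps
  par_ch <- setdiff(names(caps), "farred")
  led_par <- sum(caps[par_ch] * led_channels[par_ch] / 100)
  params$light_transmissivity * scr * par_outside +
    ifelse(hps_on, params$hps_par_capacity, 0) + ifelse(led_on, led_par, 0)
}

#' One 5-minute climate step (reference implementation)
#'
#' Lumped single-node balance for temperature, CO2 and absolute humidity:
#' proportional ventilation above the ventilation line, proportional heating
#' toward the heating line with minimum-pipe power floors, proportional CO2
#' dosing toward the setpoint (daytime only), fogging toward the
#' humidity-deficit setpoint, Beer-law canopy photosynthesis as CO2 sink and
#' PAR/humidity-deficit-driven transpiration as vapour source. Controls and
#' sources are evaluated at the incoming state; exchange terms are implicit.
#' This scalar R version is the oracle for the compiled season kernel.
#'
#' @param state numeric `c(temp_in, co2_in, ah_in)` (degC, ppm, g/m3).
#' @param weather_slot list/row with `global_radiation`, `par_outside`,
#'   `temp_out`, `rh_out`, `wind`.
#' @param setpoint_slot one row of [expand_schedule()] output.
#' @param params [greenhouse_params()].
#' @param dt step, s (the twin runs at 300).
#' @param lai crop leaf area index for the day.
#' @param rd_co2 dark respiration CO2 release, g/m2/s.
#' @param crop [crop_params()].
#' @return list with `state` (updated) and `fluxes` (named numeric: `par_in`,
#'   `vent_opening`, `heat_power` W/m2, `lamp_elec` W/m2, `co2_dose` g/m2/h,
#'   `assim` umol/m2/s, `transp` g/m2/s, `co2_vent` g/m2/s, `fog` g/m2/s).
#' @export
step_climate <- function(state, weather_slot, setpoint_slot,
                         params = greenhouse_params(), dt = 300,
                         lai = 2.5, rd_co2 = 0, crop = crop_params()) {
  if (any(!is.finite(state))) stopf("non-finite climate state: [%s]",
                                    paste(signif(state, 4), collapse = ", "))
  T <- unname(state[1]); C <- unname(state[2]); AH <- unname(state[3])
  w <- weather_slot; s <- setpoint_slot
  ah_out <- sat_abs_humidity(w$temp_out) * w$rh_out / 100

  se <- s$screen_energy / 100; sb <- s$screen_blackout / 100
  scr_light <- (1 - params$screen_energy_shading * se) *
    (1 - params$screen_blackout_shading * sb)
  p_sun <- params$light_transmissivity * scr_light * w$par_outside
  p_lamp <- (if (s$hps_on) params$hps_par_capacity else 0) +
    (if (s$led_on) params$led_par_capacity else 0)
  p_in <- p_sun + p_lamp
  q_solar <- params$solar_heat_fraction * params$light_transmissivity * scr_light *
    w$global_radiation
  p_el <- (if (s$hps_on) params$hps_par_capacity / params$hps_efficacy else 0) +
    (if (s$led_on) (params$led_par_capacity + params$led_farred_capacity) /
       params$led_efficacy else 0)

  flai <- 1 - exp(-crop$k_ext * lai)
  i_abs <- p_in * flai
  fc <- C / (C + crop$co2_km)
  ft <- exp(-((T - crop$t_opt) / crop$t_width)^2)
  am <- crop$amax_ref * fc * ft * flai
  A <- if (i_abs > 0 && am > 0) (crop$alpha * i_abs * am) / (crop$alpha * i_abs + am) else 0

  u <- clamp(s$min_vent + (100 - s$min_vent) * (T - s$vent_temp) / params$p_band,
             s$min_vent, 100)
  phi <- params$leakage + (u / 100) * params$vent_area_ratio *
    (params$vent_flux_base + params$vent_flux_wind * w$wind)

  cap_tot <- params$heat_capacity_rail + params$heat_capacity_crop_pipe
  floor_p <- min(params$h_rail * max(0, s$min_rail_pipe - T) +
                   params$h_crop_pipe * max(0, s$min_crop_pipe - T), cap_tot)
  q_heat <- clamp(max(params$kp_heat * (s$heat_sp - T), floor_p), 0, cap_tot)

  u_env <- params$envelope_conductance *
    (1 - (1 - params$screen_energy_u_factor) * se) *
    (1 - (1 - params$screen_blackout_u_factor) * sb)
  g_tot <- u_env + 1200 * phi
  T_new <- (T + dt / params$air_heat_capacity *
              (q_solar + p_el + q_heat + g_tot * w$temp_out)) /
    (1 + dt * g_tot / params$air_heat_capacity)

  mpp <- CO2_PPM_TO_G_M3 * params$height
  dose <- if (s$hps_on || w$global_radiation > 5)
    s$co2_capacity / 3600 * clamp((s$co2_sp - C) / params$co2_p_band, 0, 1) else 0
  upt <- A * 44e-6 - rd_co2
  kv <- phi * CO2_PPM_TO_G_M3
  C_new <- (C + dt / mpp * (dose - upt + kv * params$co2_outside)) /
    (1 + dt * kv / mpp)

  hd <- sat_abs_humidity(T) - AH
  E <- crop$transp_par * i_abs + crop$transp_hd * max(0, hd) * flai
  fog <- params$fog_capacity / 3600 * clamp((hd - s$hd_sp) / params$fog_p_band, 0, 1)
  t_cover <- T - 0.3 * (T - w$temp_out)
  cond <- params$cover_condensance * max(0, AH - sat_abs_humidity(t_cover))
  AH_new <- (AH + dt / params$height * (E + fog - cond + phi * ah_out)) /
    (1 + dt * phi / params$height)

  list(state = c(temp_in = T_new, co2_in = C_new, ah_in = AH_new),
       fluxes = c(par_in = p_in, vent_opening = u, heat_power = q_heat,
                  lamp_elec = p_el, co2_dose = dose * 3600, assim = A,
                  transp = E, co2_vent = kv * (C_new - params$co2_outside),
                  fog = fog))
}

#' Fertigation over one irrigation turn
#'
#' Supply per turn is sized so that the drain fraction lands on the strategy's
#' target band (20-40% of supply); crop uptake equals the transpiration
#' integral since the previous turn, drain is the non-negative remainder, and
#' drain EC relaxes towards the (concentrated) root-zone equilibrium with a
#' mixing time constant.
#'
#' @param transpiration L/m2 transpired since the last turn.
#' @param drain_target target drain fraction of supply (0-1).
#' @param supply_ec dS/m of the supplied solution.
#' @param drain_ec_prev dS/m of the previous drain.
#' @param turn_days length of the turn in days (for the EC relaxation).
#' @param ec_concentration_factor root-zone EC relative to supply EC.
#' @param ec_tau_days mixing time constant, days.
#' @return named numeric: `supply`, `drain`, `uptake` (L/m2), `drain_ec` (dS/m).
#' @export
fertigation_step <- function(transpiration, drain_target = 0.30, supply_ec = 3.2,
                             drain_ec_prev = supply_ec, turn_days = 1,
                             ec_concentration_factor = 1.25, ec_tau_days = 5) {
  stopifnot(transpiration >= 0, drain_target >= 0, drain_target < 1)
  transpiration <- unname(transpiration); drain_ec_prev <- unname(drain_ec_prev)
  supply_ec <- unname(supply_ec)
  supply <- transpiration / (1 - drain_target)
  drain <- max(0, supply - transpiration)
  target <- supply_ec * ec_concentration_factor
  drain_ec <- target + (drain_ec_prev - target) * exp(-turn_days / ec_tau_days)
  c(supply = supply, drain = drain, uptake = transpiration, drain_ec = drain_ec)
}

#' Simulate indoor climate for a season
#'
#' Runs the compiled 5-minute climate kernel over a full weather series under
#' one setpoint schedule, with crop feedback (LAI, dark respiration) supplied
#' per day by a callback. This is the climate-only entry point; the coupled
#' climate-crop season lives in [run_season()].
#'
#' @param weather a `ghw_weather` series covering the schedule's season.
#' @param schedule a `ghw_schedule`.
#' @param params [greenhouse_params()].
#' @param crop [crop_params()].
#' @param crop_feedback function(date) returning `list(lai =, rd_co2 =)`;
#'   default a constant adult canopy.
#' @return list with `climate` (per-slot data.frame), `daily` (daily
#'   aggregates) and `ledger` (a `ghw_ledger`, see [resource_ledger()]).
#' @export
simulate_climate <- function(weather, schedule, params = greenhouse_params(),
                             crop = crop_params(),
                             crop_feedback = function(date) list(lai = 2.5, rd_co2 = 2e-5)) {
  slots <- expand_schedule(schedule, timestamps = weather$timestamp)
  sim_climate_slots(weather, slots, schedule, params, crop, crop_feedback)
}

# shared season climate driver; crop_feedback evaluated once per day
sim_climate_slots <- function(weather, slots, schedule, params, crop, crop_feedback) {
  n <- nrow(weather)
  stopifnot(n == nrow(slots))
  dates <- as.Date(weather$timestamp)
  udays <- unique(dates)
  day_idx <- match(dates, udays)
  hod <- as.numeric(weather$timestamp - trunc(weather$timestamp, "days"), units = "hours")
  ah_out <- sat_abs_humidity(weather$temp_out) * weather$rh_out / 100

  pars <- params
  pars$crop <- crop
  state <- c(weather$temp_out[1] + 2, params$co2_outside, 0.8 * sat_abs_humidity(weather$temp_out[1] + 2))

  cols <- c("temp_in", "co2_in", "ah_in", "par_in", "vent_opening", "heat_power",
            "lamp_elec", "co2_dose", "assim", "transp")
  acc <- matrix(NA_real_, n, length(cols), dimnames = list(NULL, cols))
  daily <- data.frame(date = udays, heat_J = 0, elec_peak_J = 0, elec_off_J = 0,
                      co2_g = 0, co2_uptake_g = 0, co2_vent_g = 0, transp_g = 0,
                      fog_g = 0, assim_ch2o_g = 0, temp_mean = NA_real_,
                      par_mol = NA_real_, lai = NA_real_)
  for (d in seq_along(udays)) {
    ii <- which(day_idx == d)
    fb <- crop_feedback(udays[d])
    r <- .climate_day_cpp(weather$global_radiation[ii], weather$par_outside[ii],
                          weather$temp_out[ii], ah_out[ii], weather$wind[ii],
                          slots$hps_on[ii], slots$led_on[ii],
                          slots$heat_sp[ii], slots$vent_temp[ii], slots$min_vent[ii],
                          slots$screen_energy[ii], slots$screen_blackout[ii],
                          slots$co2_sp[ii], slots$co2_capacity[ii], slots$hd_sp[ii],
                          slots$min_rail_pipe[ii], slots$min_crop_pipe[ii],
                          hod[ii], state[1], state[2], state[3],
                          fb$lai, fb$rd_co2, pars, 300)
    for (cn in cols) acc[ii, cn] <- r[[cn]]
    state <- r$state
    daily$heat_J[d] <- r$heat_J; daily$elec_peak_J[d] <- r$elec_peak_J
    daily$elec_off_J[d] <- r$elec_off_J; daily$co2_g[d] <- r$co2_g
    daily$co2_uptake_g[d] <- r$co2_uptake_g; daily$co2_vent_g[d] <- r$co2_vent_g
    daily$transp_g[d] <- r$transp_g; daily$fog_g[d] <- r$fog_g
    daily$assim_ch2o_g[d] <- r$assim_ch2o_g
    daily$temp_mean[d] <- mean(r$temp_in)
    daily$par_mol[d] <- sum(r$par_in) * 300 / 1e6
    daily$lai[d] <- fb$lai
  }
  climate <- data.frame(timestamp = weather$timestamp, acc)
  ledger <- resource_ledger(daily, schedule)
  list(climate = climate, daily = daily, ledger = ledger)
}

#' Season resource ledger
#'
#' Aggregates daily climate accounting into cumulative resource use: heat
#' (MJ/m2), electricity split by the 07:00-23:00 on-peak tariff clock
#' (kWh/m2), CO2 dosed (kg/m2), and the fertigation water balance (supply,
#' drain and crop uptake, L/m2) with `uptake = supply - drain` by
#' construction.
#'
#' @param daily daily aggregate table from the climate simulation.
#' @param schedule the `ghw_schedule` (for drain target and supply EC).
#' @return a `ghw_ledger` list.
#' @export
resource_ledger <- function(daily, schedule) {
  transp_L <- daily$transp_g / 1000
  supply <- transp_L / (1 - schedule$drain_target)
  drain <- supply - transp_L
  structure(list(
    heat = sum(daily$heat_J) / 1e6,                    # MJ/m2
    electricity_peak = sum(daily$elec_peak_J) / 3.6e6, # kWh/m2
    electricity_offpeak = sum(daily$elec_off_J) / 3.6e6,
    co2_dosed = sum(daily$co2_g) / 1000,               # kg/m2
    water_supplied = sum(supply),
    water_drained = sum(drain),
    water_uptake = sum(transp_L),
    supply_ec = schedule$supply_ec,
    daily_supply = supply, daily_drain = drain
  ), class = "ghw_ledger")
}

#' Daily-aggregate climate CSV
#'
#' Writes the daily derived quantities the experiment reported: PAR sum
#' (mol/m2/d), heating energy (kWh/m2/d), electricity (kWh/m2/d), CO2 dosage
#' (kg/m2/d) and water supply (L/m2/d).
#'
#' @param daily daily table from [simulate_climate()] / [run_season()].
#' @param schedule the schedule used (drain target sizes the water columns).
#' @param path file path.
#' @export
write_daily_climate_csv <- function(daily, schedule, path) {
  transp_L <- daily$transp_g / 1000
  out <- data.frame(
    date = daily$date,
    par_sum_mol = daily$par_mol,
    heat_kwh = daily$heat_J / 3.6e6,
    electricity_kwh = (daily$elec_peak_J + daily$elec_off_J) / 3.6e6,
    co2_kg = daily$co2_g / 1000,
    water_supply_L = transp_L / (1 - schedule$drain_target),
    temp_mean = daily$temp_mean
  )
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
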