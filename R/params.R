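#' Greenhouse construction and equipment parameters
#'
#' Defaults describe one 96 m2 Venlo-type compartment: 6 HPS lamps (100
#' umol/m2/s PAR) plus 8 multi-spectrum LED lamps (109 umol/m2/s of which 12
#' far-red, not counted as PAR), rail/crop-pipe heating of 180 + 30 W/m2,
#' continuous roof ventilation of 0.3 m2 opening per m2 floor, fogging 330
#' g/m2/h and CO2 supply 15 g/m2/h. Envelope conductance and transmissivity
#' are typical Venlo values (not printed for these compartments) and are the
#' main calibration parameters of the climate twin; lamp electrical
#' efficacies (HPS 1.8, LED 2.5 umol/J) set the electricity bill.
#'
#' @param ... named overrides of any default listed below.
#' @return a `ghw_params` list.
#' @export
greenhouse_params <- function(...) {
  p <- list(
    floor_area = 96,              # m2
    height = 4,                   # m, mean air volume per m2 floor
    light_transmissivity = 0.65,  # cover + structure, fraction
    vent_area_ratio = 0.3,        # m2 opening per m2 floor
    hps_par_capacity = 100,       # umol/m2/s
    led_par_capacity = 97,        # umol/m2/s PAR (excl. far-red)
    led_farred_capacity = 12,     # umol/m2/s, counted for electricity only
    led_channel_caps = c(blue = 11, red = 49, farred = 12, white = 37),
    heat_capacity_rail = 180,     # W/m2
    heat_capacity_crop_pipe = 30, # W/m2
    co2_dose_capacity = 15,       # g/m2/h equipment maximum
    fog_capacity = 330,           # g/m2/h
    hps_efficacy = 2.1,           # umol/J electric
    led_efficacy = 3.0,           # umol/J electric
    envelope_conductance = 6.5,   # W/m2/K, cover area folded in
    screen_energy_u_factor = 0.55, # envelope conductance multiplier, closed
    screen_blackout_u_factor = 0.7,
    screen_energy_shading = 0.47, # light blocked when fully closed
    screen_blackout_shading = 0.99,
    solar_heat_fraction = 0.70,   # share of transmitted global becoming sensible heat
    air_heat_capacity = 40000,    # J/m2/K lumped (air + crop + floor buffer)
    p_band = 4,                   # degC proportional ventilation band
    kp_heat = 30,                 # W/m2/K proportional heating gain
    h_rail = 5.1,                 # W/m2/K pipe-to-air, rail (min-pipe floor)
    h_crop_pipe = 1.2,            # W/m2/K pipe-to-air, crop pipe
    leakage = 4e-4,               # m3/m2/s infiltration
    vent_flux_base = 0.05,        # m3/m2/s per unit opening ratio, calm
    vent_flux_wind = 0.0075,      # + per m/s wind
    cover_condensance = 0.008,    # m3/m2/s condensation exchange to cover
    co2_outside = 410,            # ppm
    co2_p_band = 50,              # ppm proportional dosing band
    fog_p_band = 2                # g/m3 proportional fogging band
  )
  ov <- list(...)
  stopifnot(all(names(ov) %in% names(p)))
  p[names(ov)] <- ov
  stopifnot(p$light_transmissivity > 0, p$light_transmissivity < 1)
  class(p) <- "ghw_params"
  p
}

#' Crop model parameters
#'
#' Source-sink cherry-tomato parameters: Beer-law canopy light interception,
#' a rectangular-hyperbola gross photosynthesis response with a CO2-saturating
#' asymptote and a temperature plateau over 18-24 degC, Q10 maintenance
#' respiration, partitioning proportional to potential (sink) growth rates,
#' linear temperature-driven truss initiation through the anchors 1.1
#' trusses/week @ 19 degC and 1.47 @ 24 degC, a juvenile first-truss delay,
#' and ripening on physiological fruit age (temperature sum above 4 degC,
#' threshold 55 days at 21 degC).
#'
#' @param ... named overrides.
#' @return a `ghw_crop_params` list.
#' @export
crop_params <- function(...) {
  p <- list(
    k_ext = 0.7,                # Beer-law canopy extinction
    alpha = 0.095,              # umol CO2 / umol photons, initial slope
    amax_ref = 62,              # umol CO2/m2/s asymptote at closed canopy, saturating CO2
    co2_km = 300,               # ppm half-saturation of the asymptote
    t_opt = 21, t_width = 16,   # Gaussian temperature plateau (flat +/-5% 18-24)
    maint_veg = 0.010,          # g CH2O / g DM / d at 20 degC
    maint_fruit = 0.006,
    q10 = 2.0,
    growth_yield = 0.72,        # g DM per g CH2O
    rgr_max = 0.18,             # 1/d juvenile potential relative growth rate
    veg_pot_per_stem = 0.45,    # g DM/stem/d adult vegetative sink
    fruit_pot_peak = 0.06,      # g DM/fruit/d at the sink-curve peak
    fruit_max_dm = 1.25,        # g DM genetic fruit-size cap (~13.9 g fresh)
    sink_p = 1.2, sink_q = 0.5, # fruit sink-age curve x^p (1-x)^q (normalised)
    init_veg_biomass = 12,      # g DM/m2 at planting
    sla = 0.028,                # m2 leaf / g DM
    leaf_fraction = 0.60,       # leaf share of vegetative pool
    lai_max = 3.5,              # pruning-maintained ceiling
    truss_rate_base = 1.1,      # trusses/stem/week at 19 degC
    truss_rate_slope = 0.074,   # per degC
    truss_rate_t0 = 19,
    juvenile_delay_weeks = 0.735,  # calendar delay before first truss
    ripen_base_temp = 4,        # degC base for physiological age
    ripen_sum = 810,            # degC d: ~46 d at 21.5 degC truss initiation to harvest
    dm_fraction = 0.090,        # fruit dry matter fraction
    transp_par = 1.45e-4,       # g H2O per umol absorbed PAR
    transp_hd = 3.4e-3,         # g H2O/m2/s per g/m3 humidity deficit, closed canopy
    dark_resp_frac = 1.0        # share of maintenance respired continuously
  )
  ov <- list(...)
  stopifnot(all(names(ov) %in% names(p)))
  p[names(ov)] <- ov
  class(p) <- "ghw_crop_params"
  p
}

#' Fruit-quality parameters
#'
#' Brix is modelled as a cultivar base (8.7 for this cherry type) plus a
#' dry-matter deviation term and a bounded per-strategy modifier, with seeded
#' harvest-to-harvest noise. Deliberately *not* a function of drain EC: no
#' EC-Brix effect exists for this cultivar, and the analysis module's windowed
#' EC-Brix correlation is expected to find none on simulated output.
#'
#' @param ... named overrides.
#' @return a `ghw_quality_params` list.
#' @export
quality_params <- function(...) {
  p <- list(
    brix_base = 8.7,
    brix_sd = 0.3,             # degBrix noise per harvest record
    brix_dm_coef = 20,         # degBrix per unit dry-matter-fraction deviation
    dm_reference = 0.090,
    strategy_modifier = 0.0    # degBrix, per-preset, bounded +/-0.8
  )
  ov <- list(...)
  stopifnot(all(names(ov) %in% names(p)))
  p[names(ov)] <- ov
  if (abs(p$strategy_modifier) > 0.8)
    stopf("strategy_modifier %.2f outside +/-0.8 degBrix", p$strategy_modifier)
  class(p) <- "ghw_quality_params"
  p
}

#' Seasonal Brix-dependent price model
#'
#' Weekly base price declining from winter towards summer plus a linear Brix
#' premium around a reference Brix, floored. The default calibration places
#' the six preset incomes inside the published 33.00-37.22 EUR/m2 envelope;
#' see `inst/extdata/preset-calibration.csv`.
#'
#' @param season_start,season_end season calendar used for the week index.
#' @param base_start EUR/kg in the first season week.
#' @param base_slope EUR/kg decline per week (>= 0).
#' @param brix_premium EUR/kg per degBrix above `brix_reference`.
#' @param brix_reference degBrix.
#' @param floor_price EUR/kg.
#' @return a `ghw_price_model` list.
#' @export
price_model <- function(season_start = as.Date("2019-12-16"),
                        season_end = as.Date("2020-05-29"),
                        base_start = 3.62, base_slope = 0.069,
                        brix_premium = 0.15, brix_reference = 8.7,
                        floor_price = 1.20) {
  nw <- n_season_weeks(season_start, season_end)
  weekly_base <- pmax(base_start - base_slope * (seq_len(nw) - 1), floor_price)
  structure(list(season_start = as.Date(season_start),
                 weekly_base = weekly_base,
                 brix_premium = brix_premium,
                 brix_reference = brix_reference,
                 floor_price = floor_price),
            class = "ghw_price_model")
}

#' Resource tariffs
#'
#' The published operational tariffs: electricity 0.08 EUR/kWh on-peak
#' (07:00-23:00) and 0.04 off-peak, heat 0.03 EUR/kWh, CO2 0.08 EUR/kg up to
#' 12 kg/m2 and 0.20 above, crop-maintenance labor 0.0085 EUR per stem per m2
#' per day, young plants 2.00 EUR (1-stem) or 2.20 EUR (2-stem). Water and
#' nutrient unit prices were not published and default to zero.
#'
#' @param ... named overrides.
#' @return a `ghw_tariffs` list.
#' @export
tariffs <- function(...) {
  p <- list(elec_peak = 0.08, elec_offpeak = 0.04,  # EUR/kWh
            heat = 0.03,                            # EUR/kWh
            co2_low = 0.08, co2_high = 0.20, co2_break = 12,  # EUR/kg, kg/m2
            labor_per_stem_day = 0.0085,            # EUR/stem/m2/d
            plant_1stem = 2.00, plant_2stem = 2.20, # EUR/plant
            water_per_m3 = 0, nutrients_per_kg = 0)
  ov <- list(...)
  stopifnot(all(names(ov) %in% names(p)))
  p[names(ov)] <- ov
  class(p) <- "ghw_tariffs"
  p
}
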