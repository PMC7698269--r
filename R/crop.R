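#' Temperature-driven truss initiation rate
#'
#' Linear in diurnal average temperature through the two anchors for this
#' cherry cultivar: 1.1 trusses/stem/week at 19 degC and 1.47 at 24 degC
#' (slope 0.074 trusses/week/degC). Inputs outside 15-30 degC are clamped
#' with a warning.
#'
#' @param t_avg diurnal average temperature, degC.
#' @param params [crop_params()].
#' @return trusses per stem per week.
#' @examples
#' truss_initiation_rate(19)   # 1.1
#' truss_initiation_rate(24)   # 1.47
#' @export
truss_initiation_rate <- function(t_avg, params = crop_params()) {
  if (any(t_avg < 15 | t_avg > 30)) {
    warnf("diurnal average temperature clamped to [15, 30] degC")
    t_avg <- clamp(t_avg, 15, 30)
  }
  params$truss_rate_base + params$truss_rate_slope * (t_avg - params$truss_rate_t0)
}

#' Closed-form trusses-per-stem prediction
#'
#' At a constant diurnal average temperature, final trusses per stem =
#' rate(T) x (weeks from planting to topping - juvenile delay). The single
#' juvenile-delay parameter is fitted once, by inverting this identity on a
#' reference crop.
#'
#' @param t_avg constant diurnal average temperature, degC.
#' @param planting_date,topping_date calendar (`Date` or string).
#' @param delay_weeks juvenile first-truss delay, weeks.
#' @param params [crop_params()].
#' @return predicted trusses per stem.
#' @export
predict_trusses_per_stem <- function(t_avg, planting_date, topping_date,
                                     delay_weeks = crop_params()$juvenile_delay_weeks,
                                     params = crop_params()) {
  weeks <- as.numeric(as.Date(topping_date) - as.Date(planting_date)) / 7
  truss_initiation_rate(t_avg, params) * (weeks - delay_weeks)
}

#' @rdname predict_trusses_per_stem
#' @param trusses_per_stem observed final truss count of the reference crop.
#' @export
fit_juvenile_delay <- function(trusses_per_stem, t_avg, planting_date, topping_date,
                               params = crop_params()) {
  weeks <- as.numeric(as.Date(topping_date) - as.Date(planting_date)) / 7
  weeks - trusses_per_stem / truss_initiation_rate(t_avg, params)
}

#' Canopy gross photosynthesis
#'
#' Beer-law interception of PAR over the leaf area index; the leaf response is
#' a rectangular hyperbola in absorbed PAR whose asymptote saturates in CO2
#' (Michaelis constant 300 ppm) and is flat within ~5% over 18-24 degC,
#' declining outside.
#'
#' @param par_in PAR at crop level, umol/m2/s.
#' @param co2_in ppm.
#' @param temp_in degC.
#' @param lai m2/m2.
#' @param params [crop_params()].
#' @return gross assimilation, g CH2O/m2/h.
#' @export
canopy_photosynthesis <- function(par_in, co2_in, temp_in, lai,
                                  params = crop_params()) {
  stopifnot(all(par_in >= 0), all(co2_in >= 0), all(lai >= 0))
  flai <- 1 - exp(-params$k_ext * lai)
  i_abs <- par_in * flai
  fc <- co2_in / (co2_in + params$co2_km)
  ft <- exp(-((temp_in - params$t_opt) / params$t_width)^2)
  am <- params$amax_ref * fc * ft * flai
  a <- ifelse(i_abs > 0 & am > 0, (params$alpha * i_abs * am) / (params$alpha * i_abs + am), 0)
  a * 3600 * 30e-6
}

# normalised fruit sink-age curve: x^p (1-x)^q scaled to peak 1 on (0,1)
sink_curve <- function(x, p = 1.2, q = 0.5) {
  xs <- p / (p + q)
  peak <- xs^p * (1 - xs)^q
  ifelse(x > 0 & x < 1, (x^p * (1 - x)^q) / peak, 0)
}

#' Initial crop state
#'
#' @param plan a `ghw_plan`.
#' @param params [crop_params()].
#' @return a `ghw_crop_state` list: vegetative and fruit dry-matter pools,
#'   LAI, stem cohorts, per-truss records and cumulative harvest counters.
#' @export
new_crop_state <- function(plan, params = crop_params()) {
  cohorts <- data.frame(id = 1L, start_date = plan$planting_date,
                        stems = plan$initial_stem_density, cum_trusses = 0)
  structure(list(
    veg_biomass = params$init_veg_biomass,
    fruit_biomass = 0,
    lai = min(params$lai_max,
              params$sla * params$leaf_fraction * params$init_veg_biomass),
    cohorts = cohorts,
    trusses = data.frame(cohort = integer(), init_date = as.Date(character()),
                         fruits = numeric(), age = numeric(),
                         mass_per_truss = numeric(), harvested = logical()),
    discarded_ch2o = 0,
    cum_trusses_harvested = 0, cum_yield_kg = 0
  ), class = "ghw_crop_state")
}

#' Current plant load
#'
#' Concurrently growing fruits per m2: sum over unharvested trusses of fruit
#' count times the cohort stem density.
#'
#' @param state a `ghw_crop_state`.
#' @return fruits/m2.
#' @export
plant_load <- function(state) {
  tr <- state$trusses
  if (nrow(tr) == 0) return(0)
  act <- !tr$harvested
  if (!any(act)) return(0)
  stems <- state$cohorts$stems[match(tr$cohort[act], state$cohorts$id)]
  sum(tr$fruits[act] * stems)
}

#' Apply dated crop-management actions
#'
#' Stem-density increases take effect on their dates by opening a new stem
#' cohort (released side shoots begin initiating trusses immediately, after
#' the juvenile delay); fruit pruning is enforced when each truss is created,
#' trimmed to the plan target and hard-capped at 16 (single) / 20 (split)
#' fruits regardless of the plan.
#'
#' @param state a `ghw_crop_state`.
#' @param plan a `ghw_plan`.
#' @param date current `Date`.
#' @return updated state.
#' @export
apply_crop_actions <- function(state, plan, date) {
  chg <- plan$stem_density_changes
  due <- which(chg$date == date)
  for (i in due) {
    cur <- sum(state$cohorts$stems)
    add <- chg$stems[i] - cur
    if (add > 1e-9) {
      state$cohorts <- rbind(state$cohorts,
                             data.frame(id = max(state$cohorts$id) + 1L,
                                        start_date = date, stems = add,
                                        cum_trusses = 0))
    } else if (add < -1e-9) {
      # density reductions: scale the youngest cohort down
      last <- nrow(state$cohorts)
      state$cohorts$stems[last] <- max(0, state$cohorts$stems[last] + add)
    }
  }
  state
}

#' One day of truss initiation, ageing and harvest
#'
#' Each stem cohort initiates trusses at the temperature-linear rate until
#' the topping date, starting after its juvenile delay; every truss
#' accumulates physiological age as the temperature sum above the base
#' temperature and is harvested per truss once the age passes the ripening
#' threshold (calibrated to ~55 days at 21 degC). Fresh weight converts truss
#' dry mass through the fruit dry-matter fraction.
#'
#' @param state a `ghw_crop_state`.
#' @param t_mean day-average temperature, degC.
#' @param date current `Date`.
#' @param plan a `ghw_plan`.
#' @param params [crop_params()].
#' @return list with updated `state` and a `harvests` data.frame (possibly
#'   zero rows) with `date`, `trusses_harvested` (#/m2), `fresh_weight`
#'   (kg/m2), `mean_fruit_weight` (g), `fruit_growth_period` (d).
#' @export
develop_and_harvest <- function(state, t_mean, date, plan, params = crop_params()) {
  cap <- max_fruits_per_truss(plan$truss_type)
  fruits_new <- min(plan$fruits_per_truss_target, cap)
  delay_days <- params$juvenile_delay_weeks * 7

  # initiation (suspended after topping)
  if (date <= plan$topping_date) {
    rate_day <- truss_initiation_rate(clamp(t_mean, 15, 30), params) / 7
    for (k in seq_len(nrow(state$cohorts))) {
      if (as.numeric(date - state$cohorts$start_date[k]) < delay_days) next
      prev <- state$cohorts$cum_trusses[k]
      new_cum <- prev + rate_day
      n_new <- floor(new_cum) - floor(prev)
      if (n_new >= 1) {
        add <- data.frame(cohort = rep(state$cohorts$id[k], n_new),
                          init_date = date, fruits = fruits_new, age = 0,
                          mass_per_truss = 0, harvested = FALSE)
        state$trusses <- rbind(state$trusses, add)
      }
      state$cohorts$cum_trusses[k] <- new_cum
    }
  }

  # physiological ageing
  if (nrow(state$trusses) > 0) {
    act <- !state$trusses$harvested
    state$trusses$age[act] <- state$trusses$age[act] +
      max(0, t_mean - params$ripen_base_temp)
  }

  # per-truss harvest on physiological age
  harvests <- data.frame(date = as.Date(character()), trusses_harvested = numeric(),
                         fresh_weight = numeric(), mean_fruit_weight = numeric(),
                         fruit_growth_period = numeric())
  if (nrow(state$trusses) > 0 && date <= plan$last_harvest_date) {
    ripe <- which(!state$trusses$harvested & state$trusses$age >= params$ripen_sum)
    if (length(ripe) > 0) {
      tr <- state$trusses[ripe, ]
      stems <- state$cohorts$stems[match(tr$cohort, state$cohorts$id)]
      dm_mass <- tr$mass_per_truss * stems            # g DM/m2
      fresh_kg <- dm_mass / params$dm_fraction / 1000 # kg/m2
      harvests <- data.frame(
        date = date,
        trusses_harvested = sum(stems),
        fresh_weight = sum(fresh_kg),
        mean_fruit_weight = sum(tr$mass_per_truss / params$dm_fraction) /
          sum(tr$fruits),
        fruit_growth_period = mean(as.numeric(date - tr$init_date)))
      state$trusses$harvested[ripe] <- TRUE
      state$fruit_biomass <- max(0, state$fruit_biomass - sum(dm_mass))
      state$cum_trusses_harvested <- state$cum_trusses_harvested + sum(stems)
      state$cum_yield_kg <- state$cum_yield_kg + sum(fresh_kg)
    }
  }
  list(state = state, harvests = harvests)
}

#' Daily carbohydrate production, respiration and partitioning
#'
#' Maintenance respiration scales with biomass and Q10 temperature response;
#' the remaining carbohydrates are partitioned between the vegetative pool
#' and the individual trusses proportionally to their potential (sink) growth
#' rates. Growth is capped at the summed potential: a juvenile or freshly
#' topped crop is sink limited and the surplus assimilate is discarded (it
#' buys nothing), which is what makes early- and late-season supplemental
#' light unprofitable. When respiration exceeds assimilation the pools shrink
#' by the deficit (remobilisation at no synthesis cost).
#'
#' @param state a `ghw_crop_state`.
#' @param gross_ch2o g CH2O/m2/day gross assimilation (sum of hourly rates).
#' @param t_mean day-average temperature, degC.
#' @param params [crop_params()].
#' @return updated state; attribute `"carbon"` carries the day's ledger row
#'   (`gross`, `respiration`, `growth_ch2o`, `discard`, all g CH2O/m2/d).
#' @export
daily_carbon_update <- function(state, gross_ch2o, t_mean, params = crop_params()) {
  q <- params$q10^((t_mean - 20) / 10)
  resp <- q * (params$maint_veg * state$veg_biomass +
                 params$maint_fruit * state$fruit_biomass)
  net <- gross_ch2o - resp

  act <- which(!state$trusses$harvested)
  pot_tr <- numeric(length(act))
  if (length(act) > 0) {
    tr <- state$trusses[act, ]
    stems <- state$cohorts$stems[match(tr$cohort, state$cohorts$id)]
    # genetic fruit-size cap: sink fades as fruits approach their max dry mass
    m_fruit <- tr$mass_per_truss / pmax(tr$fruits, 1)
    size_room <- clamp((params$fruit_max_dm - m_fruit) / (0.15 * params$fruit_max_dm), 0, 1)
    pot_tr <- tr$fruits * stems * params$fruit_pot_peak * size_room *
      sink_curve(tr$age / params$ripen_sum, params$sink_p, params$sink_q)
  }
  pot_fruit <- sum(pot_tr)
  pot_veg <- min(params$rgr_max * state$veg_biomass,
                 params$veg_pot_per_stem * sum(state$cohorts$stems))

  growth_ch2o <- 0; discard <- 0
  if (net >= 0) {
    demand <- (pot_fruit + pot_veg) / params$growth_yield
    growth_ch2o <- min(net, demand)
    discard <- net - growth_ch2o
    if (demand > 0) {
      dm <- params$growth_yield * growth_ch2o
      f_share <- pot_fruit / (pot_fruit + pot_veg)
      d_fruit <- dm * f_share
      state$veg_biomass <- state$veg_biomass + dm * (1 - f_share)
      if (pot_fruit > 0 && d_fruit > 0) {
        w <- pot_tr / pot_fruit
        tr <- state$trusses[act, ]
        stems <- state$cohorts$stems[match(tr$cohort, state$cohorts$id)]
        state$trusses$mass_per_truss[act] <-
          state$trusses$mass_per_truss[act] + d_fruit * w / stems
        state$fruit_biomass <- state$fruit_biomass + d_fruit
      }
    }
  } else {
    deficit <- -net   # g CH2O remobilised 1:1 from dry matter, veg first
    from_veg <- min(deficit, state$veg_biomass)
    state$veg_biomass <- state$veg_biomass - from_veg
    rem <- deficit - from_veg
    if (rem > 0 && state$fruit_biomass > 0) {
      shrink <- min(1, rem / state$fruit_biomass)
      state$trusses$mass_per_truss <- state$trusses$mass_per_truss * (1 - shrink)
      state$fruit_biomass <- state$fruit_biomass * (1 - shrink)
    }
    growth_ch2o <- net  # negative: remobilised
  }
  state$discarded_ch2o <- state$discarded_ch2o + discard
  # weekly leaf pruning folded into the LAI ceiling: vegetative biomass above
  # the ceiling is removed from the crop (it no longer respires)
  veg_max <- params$lai_max / (params$sla * params$leaf_fraction)
  if (state$veg_biomass > veg_max) {
    state$pruned_biomass <- (state$pruned_biomass %||% 0) +
      (state$veg_biomass - veg_max)
    state$veg_biomass <- veg_max
  }
  state$lai <- min(params$lai_max,
                   params$sla * params$leaf_fraction * state$veg_biomass)
  attr(state, "carbon") <- c(gross = gross_ch2o, respiration = resp,
                             growth_ch2o = growth_ch2o, discard = discard)
  state
}

#' Crop transpiration and CO2 exchange for one climate slot
#'
#' Transpiration is proportional to absorbed PAR plus a humidity-deficit term
#' over the intercepting canopy; CO2 exchange is gross assimilation in CO2
#' mass units minus continuous dark respiration (net release, i.e. a negative
#' uptake, in the dark).
#'
#' @param state a `ghw_crop_state`.
#' @param climate_slot list/row with `par_in`, `co2_in`, `temp_in`, `ah_in`.
#' @param params [crop_params()].
#' @param dt slot length, s.
#' @return named numeric: `transpiration_g` (g H2O/m2/slot) and
#'   `co2_uptake_g` (g CO2/m2/slot, negative at night).
#' @export
transpiration_and_co2_uptake <- function(state, climate_slot,
                                         params = crop_params(), dt = 300) {
  flai <- 1 - exp(-params$k_ext * state$lai)
  i_abs <- climate_slot$par_in * flai
  hd <- max(0, sat_abs_humidity(climate_slot$temp_in) - climate_slot$ah_in)
  e <- params$transp_par * i_abs + params$transp_hd * hd * flai
  a_gross <- canopy_photosynthesis(climate_slot$par_in, climate_slot$co2_in,
                                   climate_slot$temp_in, state$lai, params) / 3600 # g CH2O/s
  rd <- dark_respiration_co2(state, climate_slot$temp_in, params)
  c(transpiration_g = e * dt,
    co2_uptake_g = (a_gross * 44 / 30 - rd) * dt)
}

# continuous dark respiration as CO2 release, g CO2/m2/s
dark_respiration_co2 <- function(state, temp, params) {
  q <- params$q10^((temp - 20) / 10)
  rm <- q * (params$maint_veg * state$veg_biomass +
               params$maint_fruit * state$fruit_biomass)  # g CH2O/m2/d
  params$dark_resp_frac * rm / 86400 * 44 / 30
}
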