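test_that("par_inside reproduces the lamp and transmission arithmetic", {
  expect_identical(par_inside(0), 0)
  expect_equal(par_inside(0, hps_on = TRUE, led_on = TRUE), 197)  # far-red excluded
  expect_equal(par_inside(1000), 650)                             # transmissivity 0.65
  expect_equal(par_inside(1000, hps_on = TRUE), 750)
  expect_error(par_inside(-5), "non-negative")
})

const_slot <- function(heat_sp = -50, vent_temp = -50, min_vent = 100,
                       hps_on = FALSE, led_on = FALSE, co2_sp = 410,
                       co2_capacity = 0, hd_sp = 100) {
  list(hps_on = hps_on, led_on = led_on, heat_sp = heat_sp, vent_temp = vent_temp,
       min_vent = min_vent, screen_energy = 0, screen_blackout = 0,
       hd_sp = hd_sp, co2_sp = co2_sp, co2_capacity = co2_capacity,
       min_rail_pipe = 0, min_crop_pipe = 0, irrigation_interval = 180)
}
const_weather <- function(G = 300, temp = 10, rh = 80, wind = 3)
  list(global_radiation = G, par_outside = G, temp_out = temp, rh_out = rh, wind = wind)

test_that("passive greenhouse converges to the closed-form steady state", {
  params <- greenhouse_params()
  w <- const_weather(G = 300, temp = 10, wind = 3)
  s <- const_slot()       # no heating, vents fully open, lamps off
  st <- c(15, 410, 5)
  for (i in 1:400) st <- step_climate(st, w, s, params, lai = 2)$state
  phi <- params$leakage + 1 * params$vent_area_ratio *
    (params$vent_flux_base + params$vent_flux_wind * 3)
  g_tot <- params$envelope_conductance + 1200 * phi
  q_solar <- params$solar_heat_fraction * params$light_transmissivity * 300
  expect_equal(unname(st[1]), 10 + q_solar / g_tot, tolerance = 1e-8)
  # no radiation: indoor relaxes exactly to outside temperature
  st2 <- c(25, 410, 5)
  w0 <- const_weather(G = 0, temp = 10)
  for (i in 1:400) st2 <- step_climate(st2, w0, s, params, lai = 2)$state
  expect_equal(unname(st2[1]), 10, tolerance = 1e-8)
})

test_that("dosing at full 15 g/m2/h capacity for one hour adds 15 g", {
  params <- greenhouse_params()
  s <- const_slot(hps_on = TRUE, co2_sp = 1e5, co2_capacity = 15, min_vent = 0,
                  vent_temp = 50)
  w <- const_weather(G = 0, temp = 18)
  st <- c(20, 410, 5); dosed <- 0
  for (i in 1:12) {       # 12 x 5 min
    r <- step_climate(st, w, s, params, lai = 0)   # no crop uptake
    dosed <- dosed + r$fluxes["co2_dose"] * 300 / 3600
    st <- r$state
  }
  expect_equal(unname(dosed), 15, tolerance = 1e-9)
})

test_that("R step and compiled day kernel agree slot for slot", {
  w <- short_weather(seed = 4, end = "2019-12-17")
  pr <- make_preset(305)
  slots <- expand_schedule(pr$schedule, timestamps = w$timestamp)
  sim <- simulate_climate(w, pr$schedule,
                          crop_feedback = function(d) list(lai = 2.1, rd_co2 = 1.5e-5))
  st <- c(w$temp_out[1] + 2, 410, 0.8 * 17.3)
  # re-derive the exact kernel initial state
  st <- c(w$temp_out[1] + 2, greenhouse_params()$co2_outside,
          0.8 * tomatotwin:::sat_abs_humidity(w$temp_out[1] + 2))
  crop <- crop_params()
  for (i in 1:288) {
    r <- step_climate(st, w[i, ], slots[i, ], dt = 300, lai = 2.1, rd_co2 = 1.5e-5,
                      crop = crop)
    expect_equal(unname(r$state[1]), sim$climate$temp_in[i], tolerance = 1e-10)
    expect_equal(unname(r$state[2]), sim$climate$co2_in[i], tolerance = 1e-9)
    expect_equal(unname(r$state[3]), sim$climate$ah_in[i], tolerance = 1e-10)
    expect_equal(unname(r$fluxes["heat_power"]), sim$climate$heat_power[i],
                 tolerance = 1e-10)
    expect_equal(unname(r$fluxes["assim"]), sim$climate$assim[i], tolerance = 1e-10)
    st <- r$state
  }
})

test_that("non-finite state aborts with a diagnostic", {
  expect_error(step_climate(c(NaN, 410, 5), const_weather(), const_slot()),
               "non-finite")
})

test_that("climate-only season: electricity, monotonicity, determinism", {
  w <- short_weather(seed = 6, end = "2019-12-22")
  dark <- new_schedule(season_start = "2019-12-16", season_end = "2019-12-22",
                       weekly_hours = 0)
  r0 <- simulate_climate(w, dark)
  expect_identical(r0$ledger$electricity_peak, 0)
  expect_identical(r0$ledger$electricity_offpeak, 0)

  s10 <- new_schedule(season_start = "2019-12-16", season_end = "2019-12-22",
                      weekly_hours = 10)
  s20 <- new_schedule(season_start = "2019-12-16", season_end = "2019-12-22",
                      weekly_hours = 20)
  e10 <- with(simulate_climate(w, s10)$ledger, electricity_peak + electricity_offpeak)
  e20 <- with(simulate_climate(w, s20)$ledger, electricity_peak + electricity_offpeak)
  expect_gt(e20, e10)

  r1 <- simulate_climate(w, s10); r2 <- simulate_climate(w, s10)
  expect_identical(r1$climate, r2$climate)
  expect_identical(unclass(r1$ledger), unclass(r2$ledger))
})

test_that("passive indoor temperature stays in the physical envelope", {
  w <- short_weather(seed = 9, end = "2019-12-25")
  sch <- passive_schedule("2019-12-16", "2019-12-25")
  r <- simulate_climate(w, sch)
  d <- as.Date(w$timestamp)
  for (day in unique(d)) {
    ii <- d == day
    expect_gte(mean(r$climate$temp_in[ii]), min(w$temp_out[ii]) - 0.5)
    expect_lte(mean(r$climate$temp_in[ii]), max(w$temp_out[ii]) + 15)
  }
})

test_that("raising vent_temp does not increase seasonal CO2 vent loss", {
  w <- short_weather(seed = 2, end = "2019-12-29")
  pr <- make_preset(306)
  pr$schedule$season_end <- as.Date("2019-12-29")
  pr$schedule$weekly_hours <- pr$schedule$weekly_hours[1:2]
  base <- simulate_climate(w, pr$schedule)
  warm <- pr$schedule
  warm$vent_offset <- warm$vent_offset + 2   # vent line up, heating line fixed
  up <- simulate_climate(w, warm)
  expect_lte(sum(up$daily$co2_vent_g), sum(base$daily$co2_vent_g) + 1e-9)
})

test_that("CO2 and water ledgers conserve mass to machine precision", {
  w <- short_weather(seed = 13, end = "2019-12-29")
  pr <- make_preset(302)
  pr$schedule$season_end <- as.Date("2019-12-29")
  pr$schedule$weekly_hours <- pr$schedule$weekly_hours[1:2]
  r <- simulate_climate(w, pr$schedule)
  mpp <- tomatotwin:::CO2_PPM_TO_G_M3 * greenhouse_params()$height
  delta_mass <- (tail(r$climate$co2_in, 1) - greenhouse_params()$co2_outside) * mpp
  flows <- sum(r$daily$co2_g) - sum(r$daily$co2_uptake_g) - sum(r$daily$co2_vent_g)
  expect_lt(abs(flows - delta_mass) / max(sum(r$daily$co2_g), 1), 1e-12)
  expect_equal(r$ledger$water_uptake,
               r$ledger$water_supplied - r$ledger$water_drained, tolerance = 1e-12)
})

test_that("fertigation sizes supply on the drain target and relaxes EC", {
  f <- fertigation_step(transpiration = 0, drain_target = 0.3)
  expect_equal(unname(f["drain"]), unname(f["supply"]))
  # season worked example: 533 supplied, 334 taken up -> 199 drained
  f2 <- fertigation_step(334, drain_target = 199 / 533, supply_ec = 3.2)
  expect_equal(unname(f2["supply"]), 533, tolerance = 1e-6)
  expect_equal(unname(f2["drain"]), 199, tolerance = 1e-6)
  expect_equal(unname(f2["uptake"]), unname(f2["supply"] - f2["drain"]), tolerance = 1e-9)
  # EC relaxes monotonically toward the concentrated root-zone value
  ec <- 3.2
  for (i in 1:60) ec <- fertigation_step(2, 0.3, 3.2, ec)[["drain_ec"]]
  expect_equal(ec, 3.2 * 1.25, tolerance = 1e-4)
})
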