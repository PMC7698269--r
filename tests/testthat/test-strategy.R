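test_that("presets reproduce the per-compartment crop calendar", {
  expect_identical(make_preset(303)$plan$topping_date, as.Date("2020-04-17"))
  expect_identical(make_preset(301)$plan$topping_date, as.Date("2020-04-30"))
  expect_identical(make_preset(302)$plan$topping_date, as.Date("2020-04-16"))
  expect_identical(make_preset(306)$plan$topping_date, as.Date("2020-04-21"))
  for (id in 301:306) {
    p <- make_preset(id)
    expect_identical(p$plan$planting_date, as.Date("2019-12-16"))
    expect_identical(p$plan$last_harvest_date, as.Date("2020-05-29"))
  }
  expect_error(make_preset(299), "unknown compartment")
})

test_that("presets validate cleanly and keep their qualitative ordering", {
  ps <- lapply(301:306, make_preset)
  for (p in ps) expect_identical(nrow(validate_strategy(p$schedule, p$plan)), 0L)
  hrs <- vapply(ps, function(p) sum(p$schedule$weekly_hours), 0)
  names(hrs) <- 301:306
  expect_true(hrs["305"] > max(hrs[c("301", "302", "303", "304", "306")]))
  expect_lte(max(hrs[c("302", "304")]), min(hrs[c("301", "303", "306")]))
  caps <- vapply(ps, function(p) p$schedule$co2_capacity, 0)
  names(caps) <- 301:306
  expect_true(caps["301"] >= max(caps))        # 301: very high CO2 dosing
  p303 <- ps[[3]]
  expect_true(any(p303$plan$stem_density_changes$stems == 8.0))
  expect_true(max(p303$plan$stem_density_changes$date) < p303$plan$topping_date)
  mods <- vapply(ps, function(p) p$brix_modifier, 0)
  names(mods) <- 301:306
  expect_true(mods["305"] == max(mods) && mods["303"] == min(mods))
  expect_true(all(abs(mods) <= 0.8))
})

test_that("validation reports violations without throwing", {
  slots <- expand_schedule(make_preset(306)$schedule)
  slots$led_on[5] <- TRUE; slots$hps_on[5] <- FALSE
  v <- validate_strategy(slots)
  expect_identical(nrow(v), 1L)
  expect_match(v$rule, "HPS")
  expect_identical(v$slot, 5L)

  bad_plan <- make_preset(306)$plan
  bad_plan$stem_density_changes <- data.frame(date = as.Date("2020-03-01"), stems = 9.0)
  v2 <- validate_strategy(make_preset(306)$schedule, bad_plan)
  expect_true(any(grepl("2.6-8.0", v2$rule)))
})

test_that("shift_temperature moves only the temperature lines, slot-wise", {
  s <- make_preset(304)$schedule
  expect_identical(shift_temperature(s, 0), s)
  s2 <- shift_temperature(s, -2)
  a <- expand_schedule(s); b <- expand_schedule(s2)
  expect_equal(b$vent_temp, a$vent_temp - 2)
  expect_equal(b$heat_sp, a$heat_sp - 2)
  same <- setdiff(names(a), c("vent_temp", "heat_sp", "min_rail_pipe", "min_crop_pipe"))
  expect_identical(a[same], b[same])
  # the +/-2 bound is cumulative over calls
  expect_error(shift_temperature(shift_temperature(s, 2), 2), "cumulative")
})

test_that("adjust_lighting_hours stretches the solar-noon block symmetrically", {
  s <- new_schedule(weekly_hours = 10)
  expect_identical(adjust_lighting_hours(s, 0), s)
  s2 <- adjust_lighting_hours(s, 3)
  day1 <- expand_schedule(s2)[1:288, ]
  expect_identical(sum(day1$hps_on), 13L * 12L)   # 13 h of 5-min slots
  on <- which(day1$hps_on)
  hod <- as.numeric(day1$timestamp[on] - trunc(day1$timestamp[on], "days"), units = "hours")
  expect_equal(mean(range(hod)), 12 - 1 / 24, tolerance = 0.05)  # centred on noon
  # clamped at zero with a warning
  s3 <- new_schedule(weekly_hours = 2)
  expect_warning(s4 <- adjust_lighting_hours(s3, -3), "clamped")
  expect_true(all(s4$weekly_hours == 0))
  expect_error(adjust_lighting_hours(adjust_lighting_hours(s, 2), 2), "cumulative")
})

test_that("adjust_co2 shifts the setpoint and replaces capacity", {
  s <- new_schedule(co2_sp = 800, co2_capacity = 120)
  expect_identical(adjust_co2(s, 0, 120), s)
  s2 <- adjust_co2(s, -100, 200)
  sl <- expand_schedule(s2)
  early <- sl$co2_sp[season_week_of(sl$timestamp, s$season_start) <= s$co2_taper_week]
  expect_true(all(early == 700))
  expect_true(all(sl$co2_capacity == 20))  # 200 kg/ha/h = 20 g/m2/h
  expect_error(adjust_co2(s, -150, 120), "offset")
  expect_error(adjust_co2(s, 0, 250), "capacity")
})

test_that("set_weekly_lighting_hours adds 14 lamp hours for +2 h in one week", {
  s <- make_preset(306)$schedule
  expect_identical(set_weekly_lighting_hours(s, s$weekly_hours), s)
  h <- s$weekly_hours; h[10] <- h[10] + 2
  s2 <- set_weekly_lighting_hours(s, h)
  n0 <- sum(expand_schedule(s)$hps_on)
  n2 <- sum(expand_schedule(s2)$hps_on)
  expect_identical(n2 - n0, 14L * 12L)     # 2 h/day x 7 d = 14 h = 168 slots
  # set-then-reset round-trips
  expect_identical(set_weekly_lighting_hours(s2, s$weekly_hours), s)
  expect_error(set_weekly_lighting_hours(s, h[-1]), "length")
  h[3] <- 25
  expect_error(set_weekly_lighting_hours(s, h), "0, 20")
})

test_that("strategy config round-trips losslessly", {
  for (id in c(301, 303, 306)) {
    p <- make_preset(id)
    f <- withr::local_tempfile(fileext = ".cfg")
    write_strategy(p, f)
    p2 <- read_strategy(f)
    expect_identical(p2$compartment, p$compartment)
    expect_equal(p2$brix_modifier, p$brix_modifier)
    expect_equal(p2$schedule[order(names(p2$schedule))],
                 p$schedule[order(names(p$schedule))], tolerance = 1e-12)
    expect_equal(p2$plan[order(names(p2$plan))], p$plan[order(names(p$plan))])
    # save -> load -> save is byte-identical
    f2 <- withr::local_tempfile(fileext = ".cfg")
    write_strategy(p2, f2)
    expect_identical(readLines(f), readLines(f2))
  }
})
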