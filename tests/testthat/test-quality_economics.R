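fake_harvests <- function(n = 40, start = "2020-02-13") {
  data.frame(date = as.Date(start) + seq_len(n) * 2,
             trusses_harvested = 1.5, fresh_weight = 0.15,
             mean_fruit_weight = 10, fruit_growth_period = 46)
}

test_that("assign_brix hits the base exactly when noise and modifiers are off", {
  h <- assign_brix(fake_harvests(), quality_params(brix_sd = 0), seed = 1)
  expect_true(all(h$brix == 8.7))
  h2 <- assign_brix(fake_harvests(), quality_params(brix_sd = 0, strategy_modifier = 0.4),
                    dm_fraction = 0.095, seed = 1)
  expect_true(all(h2$brix == 8.7 + 0.4 + 20 * 0.005))
  # seeded noise is reproducible
  a <- assign_brix(fake_harvests(), seed = 5); b <- assign_brix(fake_harvests(), seed = 5)
  expect_identical(a$brix, b$brix)
  expect_error(quality_params(strategy_modifier = 1.0), "0.8")
})

test_that("flavor surrogate is a bounded monotone map with rank correlation 1", {
  expect_gt(flavor_surrogate(9.5), flavor_surrogate(8.0))
  grid <- seq(4, 14, by = 0.25)
  f <- flavor_surrogate(grid)
  expect_true(all(f >= 0 & f <= 100))
  expect_true(all(diff(f) > 0))
  brix <- withr::with_seed(2, runif(50, 6, 11))
  expect_equal(cor(brix, flavor_surrogate(brix), method = "spearman"), 1)
  expect_warning(flavor_surrogate(3), "clamped")
})

test_that("pricing combines the seasonal base and the Brix premium", {
  pm <- price_model()
  expect_equal(price_of(pm$brix_reference, 9, pm), pm$weekly_base[9])
  expect_gte(price_of(8.7, 8, pm), price_of(8.7, 22, pm))   # seasonal decline
  expect_gt(price_of(9.5, 10, pm), price_of(8.5, 10, pm))
  expect_equal(price_of(0, 24, pm), pm$floor_price)         # floored
})

test_that("income is a linear, monotone aggregation of harvests", {
  pm <- price_model()
  h <- assign_brix(fake_harvests(), seed = 3)
  expect_identical(compute_income(h[0, ], pm), 0)
  base <- compute_income(h, pm)
  h2 <- h; h2$fresh_weight <- 2 * h2$fresh_weight
  expect_equal(compute_income(h2, pm), 2 * base)
  h3 <- h; h3$brix <- h3$brix + 0.5
  expect_gt(compute_income(h3, pm), base)
})

test_that("cost components reproduce the printed tariffs", {
  tf <- tariffs()
  mk_ledger <- function(co2) structure(list(heat = 0, electricity_peak = 0,
                                            electricity_offpeak = 0, co2_dosed = co2,
                                            water_supplied = 0, water_drained = 0,
                                            water_uptake = 0, supply_ec = 3.2),
                                       class = "ghw_ledger")
  plan <- new_plan(initial_stem_density = 3.8, plants_are_two_stem = TRUE)
  costs <- compute_costs(mk_ledger(14), plan, stem_days = 0, tf)
  expect_equal(costs$co2, 12 * 0.08 + 2 * 0.20)         # 1.36 at 14 kg/m2
  expect_equal(costs$plants, 3.8 / 2 * 2.20)            # 4.18
  costs2 <- compute_costs(mk_ledger(0), new_plan(initial_stem_density = 4.0),
                          stem_days = 4.0 * 10, tf)
  expect_equal(costs2$labor, 0.34)                      # 4 stems x 10 d x 0.0085
  # CO2 cost is continuous and piecewise linear with its kink at 12 kg/m2
  eps <- 1e-9
  below <- compute_costs(mk_ledger(12 - eps), plan, 0, tf)$co2
  above <- compute_costs(mk_ledger(12 + eps), plan, 0, tf)$co2
  expect_equal(below, above, tolerance = 1e-6)
  expect_equal(compute_costs(mk_ledger(6), plan, 0, tf)$co2, 6 * 0.08)
  expect_equal(compute_costs(mk_ledger(16), plan, 0, tf)$co2 -
                 compute_costs(mk_ledger(15), plan, 0, tf)$co2, 0.20)
  bad <- mk_ledger(5); bad$heat <- -1
  expect_error(compute_costs(bad, plan, 0, tf), "negative")
})

test_that("resource-use efficiencies follow the division and EC rules", {
  led <- structure(list(heat = 185.8, electricity_peak = 100, electricity_offpeak = 50,
                        co2_dosed = 9, water_supplied = 520, water_drained = 160,
                        water_uptake = 360, supply_ec = 3.32), class = "ghw_ledger")
  led$water_uptake <- 25.0 * 14.4   # so the water metric is exactly 25 L/kg
  rue <- resource_use_efficiency(led, 14.4)
  expect_equal(unname(rue["heat"]), 185.8 / 14.4)        # 12.9 MJ/kg
  expect_equal(unname(rue["water"]), 25.0)
  expect_equal(unname(rue["nutrients"]), 25.0 * 3.32)    # 83 g/kg
  expect_error(resource_use_efficiency(led, 0), "positive")
  led0 <- led; led0$heat <- 0; led0$electricity_peak <- 0
  led0$electricity_offpeak <- 0; led0$co2_dosed <- 0; led0$water_uptake <- 0
  expect_true(all(resource_use_efficiency(led0, 10)[c("heat", "electricity", "co2", "water")] == 0))
})

test_that("the accounting identity net_profit = income - costs holds exactly", {
  led <- structure(list(heat = 400, electricity_peak = 150, electricity_offpeak = 40,
                        co2_dosed = 11, water_supplied = 600, water_drained = 200,
                        water_uptake = 400, supply_ec = 3.3), class = "ghw_ledger")
  h <- assign_brix(fake_harvests(60), seed = 9)
  e <- economic_result(h, led, new_plan(initial_stem_density = 3.5), stem_days = 700)
  expect_identical(e$net_profit, e$income - e$costs$total)
  expect_identical(e$costs$total, sum(unlist(e$costs[setdiff(names(e$costs), "total")])))
})
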