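#' Assign Brix to harvest records
#'
#' Brix = cultivar base + dry-matter deviation term + per-strategy modifier +
#' seeded noise. Deliberately independent of drain EC: for this cherry
#' cultivar drain EC has no Brix effect, and the EC-Brix analysis in
#' [ec_brix_correlation()] is expected to find none on simulated seasons.
#'
#' @param harvests harvest data.frame (one row per harvest record).
#' @param quality [quality_params()].
#' @param dm_fraction realised fruit dry-matter fraction.
#' @param seed integer seed for the harvest-to-harvest noise.
#' @return the harvests data.frame with a `brix` column added.
#' @export
assign_brix <- function(harvests, quality = quality_params(),
                        dm_fraction = crop_params()$dm_fraction, seed = 1L) {
  n <- nrow(harvests)
  noise <- if (quality$brix_sd > 0) with_seed(seed, rnorm(n, sd = quality$brix_sd)) else rep(0, n)
  harvests$brix <- quality$brix_base +
    quality$brix_dm_coef * (dm_fraction - quality$dm_reference) +
    quality$strategy_modifier + noise
  harvests
}

#' Monotone flavor surrogate
#'
#' A saturating logistic map from Brix to a 0-100 liking score. This is a
#' stand-in for the laboratory flavor model (whose inputs are lab
#' measurements and which is out of scope); it preserves only the observed
#' positive Brix-flavor association.
#'
#' @param brix degBrix, expected in [4, 14] (clamped with a warning outside).
#' @return score in [0, 100].
#' @export
flavor_surrogate <- function(brix) {
  if (any(brix < 4 | brix > 14)) {
    warnf("Brix outside [4, 14] clamped for the flavor surrogate")
    brix <- clamp(brix, 4, 14)
  }
  100 * stats::plogis((brix - 8) / 1.2)
}

#' Price of a harvest
#'
#' Weekly base price (declining from winter to summer) plus a linear Brix
#' premium above the reference Brix, floored at the floor price.
#'
#' @param brix degBrix.
#' @param week season week index (1-based from the price model's season start).
#' @param pm [price_model()].
#' @return EUR/kg.
#' @export
price_of <- function(brix, week, pm = price_model()) {
  week <- clamp(as.integer(week), 1L, length(pm$weekly_base))
  pmax(pm$floor_price,
       pm$weekly_base[week] + pm$brix_premium * (brix - pm$brix_reference))
}

#' Season income
#'
#' Sum over harvest records of fresh weight times the Brix- and
#' week-dependent price.
#'
#' @param harvests harvest data.frame with `date`, `fresh_weight`, `brix`.
#' @param pm [price_model()].
#' @return EUR/m2.
#' @export
compute_income <- function(harvests, pm = price_model()) {
  if (nrow(harvests) == 0) return(0)
  wk <- season_week(harvests$date, pm$season_start)
  sum(harvests$fresh_weight * price_of(harvests$brix, wk, pm))
}

#' Season cost breakdown
#'
#' Applies the published tariffs to the resource ledger and crop plan:
#' plants at 2.00/2.20 EUR per 1-/2-stem plant, electricity split by the
#' 07:00-23:00 tariff clock, heat at 0.03 EUR/kWh, CO2 tiered at the
#' 12 kg/m2 breakpoint (0.08 then 0.20 EUR/kg), labor at 0.0085 EUR per stem
#' per m2 per day integrated over the realised stem-density trajectory, and
#' (default-zero) water/nutrient prices.
#'
#' @param ledger a `ghw_ledger`.
#' @param plan a `ghw_plan`.
#' @param stem_days stems/m2 integrated over days (sum of daily stem density).
#' @param tf [tariffs()].
#' @return named list of cost components plus `total`, all EUR/m2.
#' @export
compute_costs <- function(ledger, plan, stem_days, tf = tariffs()) {
  if (any(unlist(ledger[c("heat", "electricity_peak", "electricity_offpeak",
                          "co2_dosed", "water_supplied")]) < 0))
    stopf("negative ledger entries")
  plants_per_m2 <- plan$initial_stem_density / if (plan$plants_are_two_stem) 2 else 1
  plant_price <- if (plan$plants_are_two_stem) tf$plant_2stem else tf$plant_1stem
  co2 <- ledger$co2_dosed
  co2_cost <- tf$co2_low * min(co2, tf$co2_break) +
    tf$co2_high * max(0, co2 - tf$co2_break)
  costs <- list(
    plants = plants_per_m2 * plant_price,
    electricity_peak = ledger$electricity_peak * tf$elec_peak,
    electricity_offpeak = ledger$electricity_offpeak * tf$elec_offpeak,
    heat = ledger$heat / 3.6 * tf$heat,
    co2 = co2_cost,
    labor = tf$labor_per_stem_day * stem_days,
    water_nutrients = ledger$water_supplied / 1000 * tf$water_per_m3 +
      ledger$water_supplied / 1000 * ledger$supply_ec * tf$nutrients_per_kg
  )
  costs$total <- sum(unlist(costs))
  costs
}

#' Resource-use efficiencies
#'
#' Each season resource total divided by total yield: heat MJ/kg,
#' electricity kWh/kg, CO2 kg/kg, water L/kg and nutrients g/kg. The water
#' metric uses net crop uptake (supply minus re-used drain); nutrients follow
#' the rule-of-thumb that 1 EC unit is 1 kg dissolved salts per m3, i.e.
#' g/kg = (L/kg) x supply EC.
#'
#' @param ledger a `ghw_ledger`.
#' @param total_yield kg/m2 class-A fresh yield; must be positive.
#' @return named numeric vector.
#' @export
resource_use_efficiency <- function(ledger, total_yield) {
  if (total_yield <= 0) stopf("total_yield must be positive")
  water <- ledger$water_uptake / total_yield
  c(heat = ledger$heat / total_yield,
    electricity = (ledger$electricity_peak + ledger$electricity_offpeak) / total_yield,
    co2 = ledger$co2_dosed / total_yield,
    water = water,
    nutrients = water * ledger$supply_ec)
}

#' Assemble the economic result
#'
#' @param harvests harvest records with Brix.
#' @param ledger a `ghw_ledger`.
#' @param plan a `ghw_plan`.
#' @param stem_days integrated stems/m2 over days.
#' @param pm [price_model()].
#' @param tf [tariffs()].
#' @return a `ghw_economics` list: `income`, `costs` (breakdown), `net_profit`
#'   (= income - total costs, exact) and `rue`.
#' @export
economic_result <- function(harvests, ledger, plan, stem_days,
                            pm = price_model(), tf = tariffs()) {
  income <- compute_income(harvests, pm)
  costs <- compute_costs(ledger, plan, stem_days, tf)
  yield <- sum(harvests$fresh_weight)
  rue <- if (yield > 0) resource_use_efficiency(ledger, yield) else
    c(heat = NA, electricity = NA, co2 = NA, water = NA, nutrients = NA)
  structure(list(income = income, costs = costs,
                 net_profit = income - costs$total,
                 yield = yield, rue = rue),
            class = "ghw_economics")
}

#' @export
print.ghw_economics <- function(x, ...) {
  cat(sprintf("Season economics: yield %.2f kg/m2, income %.2f EUR/m2, costs %.2f EUR/m2, net profit %.2f EUR/m2\n",
              x$yield, x$income, x$costs$total, x$net_profit))
  cb <- unlist(x$costs[setdiff(names(x$costs), "total")])
  cat("  costs:", paste(sprintf("%s %.2f", names(cb), cb), collapse = ", "), "\n")
  if (!any(is.na(x$rue)))
    cat(sprintf("  RUE: heat %.1f MJ/kg, elec %.1f kWh/kg, CO2 %.2f kg/kg, water %.1f L/kg, nutrients %.1f g/kg\n",
                x$rue["heat"], x$rue["electricity"], x$rue["co2"], x$rue["water"], x$rue["nutrients"]))
  invisible(x)
}
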