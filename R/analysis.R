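#' Sensitivity sweeps over CO2, temperature and lighting
#'
#' Each sweep re-simulates the full season per grid point on ONE fixed
#' weather realisation (passed in, as the real analysis used the one realised
#' season) and reports the change in net profit and yield against the
#' unperturbed baseline. The zero-perturbation point reproduces the baseline
#' bit for bit because the identical schedule and weather are re-simulated
#' deterministically.
#'
#' `sweep_co2` shifts the CO2 setpoint (-100..+50 ppm) while replacing the
#' dosing capacity (50..200 kg/ha/h); offsets and capacities of equal length
#' are paired, otherwise the full grid is swept. `sweep_temperature` shifts
#' the heating/ventilation lines by -2..+2 degC. `sweep_lighting` adds
#' -3..+3 h/day to the lamp block at unchanged intensity.
#'
#' @param preset compartment id or `ghw_preset`.
#' @param offsets ppm offsets within [-100, +50].
#' @param capacities kg/ha/h within [50, 200].
#' @param deltas degC within [-2, +2].
#' @param deltas_h hours within [-3, +3].
#' @param weather fixed `ghw_weather` realisation; generated from `seed` when
#'   `NULL`.
#' @param seed integer seed (weather + Brix noise).
#' @param ... passed to [run_config()] (parameter overrides).
#' @return a `ghw_sensitivity` data.frame: perturbation columns,
#'   `delta_net_profit` and `delta_yield`, with the baseline run attached as
#'   attribute `"baseline"`.
#' @export
sweep_co2 <- function(preset, offsets = c(-100, -50, 0, 25, 50),
                      capacities = NULL, weather = NULL, seed = 1L, ...) {
  if (any(offsets < -100 | offsets > 50))
    stopf("CO2 offsets outside [-100, +50] ppm")
  pr <- as_preset(preset)
  if (is.null(capacities)) capacities <- rep(pr$schedule$co2_capacity, length(offsets))
  if (any(capacities < 50 | capacities > 200))
    stopf("CO2 capacities outside [50, 200] kg/ha/h")
  grid <- if (length(offsets) == length(capacities))
    data.frame(offset = offsets, capacity = capacities)
  else expand.grid(offset = offsets, capacity = capacities)
  run_sweep(pr, grid, weather, seed,
            function(p, row) {
              p$schedule <- adjust_co2(p$schedule, row$offset, row$capacity); p
            }, ...)
}

#' @rdname sweep_co2
#' @export
sweep_temperature <- function(preset, deltas = c(-2, -1, 0, 1, 2),
                              weather = NULL, seed = 1L, ...) {
  if (any(abs(deltas) > 2)) stopf("temperature deltas outside [-2, +2] degC")
  run_sweep(as_preset(preset), data.frame(delta = deltas), weather, seed,
            function(p, row) {
              p$schedule <- shift_temperature(p$schedule, row$delta); p
            }, ...)
}

#' @rdname sweep_co2
#' @export
sweep_lighting <- function(preset, deltas_h = c(-3, -1.5, 0, 1.5, 3),
                           weather = NULL, seed = 1L, ...) {
  if (any(abs(deltas_h) > 3)) stopf("lighting deltas outside [-3, +3] h")
  run_sweep(as_preset(preset), data.frame(delta_h = deltas_h), weather, seed,
            function(p, row) {
              p$schedule <- suppressWarnings(adjust_lighting_hours(p$schedule, row$delta_h)); p
            }, ...)
}

as_preset <- function(preset) if (inherits(preset, "ghw_preset")) preset else make_preset(preset)

run_sweep <- function(preset, grid, weather, seed, perturb, ...) {
  weather <- weather %||% generate_weather(preset$schedule$season_start,
                                           preset$schedule$season_end, seed = seed)
  base <- run_season(run_config(preset, seed = seed, weather = weather, ...))
  out <- grid
  out$net_profit <- NA_real_; out$yield <- NA_real_
  for (i in seq_len(nrow(grid))) {
    p <- perturb(preset, grid[i, , drop = FALSE])
    r <- run_season(run_config(p, seed = seed, weather = weather, ...))
    out$net_profit[i] <- r$economics$net_profit
    out$yield[i] <- r$economics$yield
  }
  out$delta_net_profit <- out$net_profit - base$economics$net_profit
  out$delta_yield <- out$yield - base$economics$yield
  structure(out, class = c("ghw_sensitivity", "data.frame"),
            baseline = base, compartment = preset$compartment, seed = seed)
}

#' Per-week marginal value of extra lighting
#'
#' Adds `added_hours` lamp hours per day to one week at a time (14 extra
#' hours per week at the default +2 h/day), re-simulates the season, and
#' reports the net-profit change per week. The characteristic shape --
#' negative in the first sink-limited weeks, peaking mid-season, dropping
#' towards the end as sunlight rises and prices fall -- is what the weekly
#' optimizer exploits.
#'
#' @param preset compartment id or `ghw_preset`.
#' @param weather fixed weather realisation (generated from `seed` if `NULL`).
#' @param seed integer seed.
#' @param added_hours h/day added to the perturbed week (default +2).
#' @param ... passed to [run_config()].
#' @return data.frame `week`, `delta_net_profit`, `delta_yield`.
#' @export
weekly_lighting_marginal <- function(preset, weather = NULL, seed = 1L,
                                     added_hours = 2, ...) {
  pr <- as_preset(preset)
  nw <- length(pr$schedule$weekly_hours)
  weather <- weather %||% generate_weather(pr$schedule$season_start,
                                           pr$schedule$season_end, seed = seed)
  base <- run_season(run_config(pr, seed = seed, weather = weather, ...))
  out <- data.frame(week = seq_len(nw), delta_net_profit = NA_real_,
                    delta_yield = NA_real_)
  for (w in seq_len(nw)) {
    h <- pr$schedule$weekly_hours
    h[w] <- clamp(h[w] + added_hours, 0, 20)
    p <- pr; p$schedule <- set_weekly_lighting_hours(p$schedule, h)
    r <- run_season(run_config(p, seed = seed, weather = weather, ...))
    out$delta_net_profit[w] <- r$economics$net_profit - base$economics$net_profit
    out$delta_yield[w] <- r$economics$yield - base$economics$yield
  }
  structure(out, baseline = base, compartment = pr$compartment)
}

#' Optimize weekly lighting hours by coordinate ascent
#'
#' Cyclically visits the season weeks, tries moving that week's lamp hours by
#' +/- `step` h/day (within [0, 20]) and keeps any move that improves
#' simulated net profit, until a full pass makes no improvement or
#' `max_iters` passes are exhausted. The objective trace is non-decreasing by
#' construction and the reported gain is always >= 0.
#'
#' @param preset compartment id or `ghw_preset`.
#' @param weather fixed weather realisation (generated from `seed` if `NULL`).
#' @param seed integer seed.
#' @param step h/day per move (> 0).
#' @param max_iters maximum number of full passes.
#' @param ... passed to [run_config()].
#' @return list: `hours_by_week` (optimized profile), `gain` (EUR/m2, >= 0),
#'   `baseline_profit`, `optimized_profit`, `trace` (accepted objectives),
#'   `evaluations`.
#' @export
optimize_weekly_lighting <- function(preset, weather = NULL, seed = 1L,
                                     step = 1, max_iters = 3, ...) {
  stopifnot(step > 0)
  pr <- as_preset(preset)
  weather <- weather %||% generate_weather(pr$schedule$season_start,
                                           pr$schedule$season_end, seed = seed)
  profit_of <- function(hours) {
    p <- pr; p$schedule <- set_weekly_lighting_hours(p$schedule, hours)
    run_season(run_config(p, seed = seed, weather = weather, ...))$economics$net_profit
  }
  hours <- clamp(pr$schedule$weekly_hours, 0, 20)
  best <- profit_of(hours)
  baseline <- best
  trace <- best
  evals <- 1L
  for (it in seq_len(max_iters)) {
    improved <- FALSE
    for (w in seq_along(hours)) {
      for (dir in c(step, -step)) {
        cand <- hours
        cand[w] <- clamp(cand[w] + dir, 0, 20)
        if (identical(cand[w], hours[w])) next
        val <- profit_of(cand); evals <- evals + 1L
        if (val > best + 1e-12) {
          hours <- cand; best <- val; trace <- c(trace, best)
          improved <- TRUE
          break
        }
      }
    }
    if (!improved) break
  }
  list(hours_by_week = hours, gain = best - baseline,
       baseline_profit = baseline, optimized_profit = best,
       trace = trace, evaluations = evals)
}

#' Windowed EC-Brix correlation
#'
#' For each harvest record, averages the drain EC over the trailing window
#' (default 35 days, the assumed fruit growth period) and correlates it with
#' the record's Brix across harvests (Pearson). With a constant Brix or
#' constant windowed EC the correlation is undefined and returned as `NA`
#' with `defined = FALSE`, not as zero.
#'
#' @param drain_ec data.frame with `date` and `ec` (dS/m), daily.
#' @param harvests harvest records with `date` and `brix`.
#' @param window_days trailing window, days.
#' @return list: `correlation`, `defined`, `n`, and the paired `table`
#'   (`date`, `brix`, `mean_ec`).
#' @export
ec_brix_correlation <- function(drain_ec, harvests, window_days = 35) {
  if (nrow(harvests) < 3) stopf("need at least 3 harvest records")
  drain_ec$date <- as.Date(drain_ec$date)
  mean_ec <- vapply(as.Date(harvests$date), function(d) {
    w <- drain_ec$ec[drain_ec$date > d - window_days & drain_ec$date <= d]
    if (length(w) == 0) NA_real_ else mean(w)
  }, 0)
  tab <- data.frame(date = harvests$date, brix = harvests$brix, mean_ec = mean_ec)
  tab <- tab[complete.cases(tab), ]
  defined <- nrow(tab) >= 3 && stats::sd(tab$brix) > 0 && stats::sd(tab$mean_ec) > 0
  r <- if (defined) cor(tab$mean_ec, tab$brix) else NA_real_
  list(correlation = r, defined = defined, n = nrow(tab), table = tab)
}

#' Simulated drain-EC series of a season run
#'
#' Relaxes drain EC towards the root-zone equilibrium day by day via
#' [fertigation_step()], producing the daily drain-EC series that pairs with
#' the run's harvest records in [ec_brix_correlation()]. The root-zone
#' concentration factor responds to the day's transpiration demand (salts
#' accumulate faster on high-uptake days), so the series carries realistic
#' weather-driven variability -- but, by design, no link to Brix.
#'
#' @param result a `ghw_season`.
#' @return data.frame `date`, `ec`.
#' @export
drain_ec_series <- function(result) {
  sch <- result$config$preset$schedule
  transp_L <- result$daily$transp_g / 1000
  ec <- numeric(length(transp_L))
  prev <- sch$supply_ec
  for (i in seq_along(ec)) {
    conc <- 1.10 + 0.10 * clamp(transp_L[i] / 3, 0, 2)
    f <- fertigation_step(transp_L[i], sch$drain_target, sch$supply_ec, prev,
                          ec_concentration_factor = conc, ec_tau_days = 3)
    ec[i] <- unname(f[["drain_ec"]]); prev <- ec[i]
  }
  data.frame(date = result$daily$date, ec = ec)
}
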