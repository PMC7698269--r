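# tomatotwin

A desk-scale digital twin of a supplementally lit Dutch greenhouse
compartment growing an indeterminate cherry-tomato crop over a
December–May season, with techno-economic scoring and sensitivity
analysis of the control strategy.

It is aimed at greenhouse-horticulture researchers and students who want a
self-contained, fully reproducible sandbox in which *control strategies* —
setpoint schedules for supplemental lighting, heating/ventilation lines,
CO₂ dosing, screens, humidity and irrigation, plus crop-management plans
(stem density, fruit pruning, topping date) — can be compared on simulated
net profit, the way autonomous-greenhouse competitions score their teams.

## What is inside

* **Synthetic weather** — seeded 5-minute outside weather for a mid-latitude
  site: clear-sky radiation from solar geometry attenuated by an AR(1)
  cloudiness process, seasonal + diurnal temperature, humidity and wind.
* **Strategies** — the challenge's setpoint vocabulary as daily templates
  with a per-week photoperiod profile, six archetype presets emulating
  greenhouse compartments 301–306, validation, and the perturbation
  operators used by the sensitivity analysis.
* **Climate twin** — a lumped single-node energy/CO₂/humidity balance at a
  5-minute step (compiled kernel, with a scalar R reference implementation
  used as its test oracle): proportional ventilation and heating control,
  screen effects, fogging, and metered resource use split by the
  07:00–23:00 electricity tariff clock.
* **Crop twin** — a source–sink cherry-tomato model: Beer-law canopy gross
  photosynthesis summed hourly, Q10 maintenance respiration, partitioning
  over vegetative and per-truss fruit sinks according to their relative
  potential growth rates, temperature-linear truss initiation
  (`rate = 1.1 + 0.074·(T − 19)` trusses/stem/week), a sink-limited
  juvenile phase, fruit pruning caps (16 fruits on single, 20 on split
  trusses), topping, and per-truss harvest on physiological fruit age
  (temperature sum above 4 °C).
* **Quality & economics** — Brix per harvest (cultivar base 8.7,
  deliberately independent of drain EC), a monotone flavor surrogate,
  seasonal Brix-dependent pricing, published operational tariffs
  (electricity 0.08/0.04 €/kWh peak/off-peak, heat 0.03 €/kWh, CO₂
  0.08 €/kg tiered at 12 kg/m², labor 0.0085 €/stem/m²/day, plants
  2.00/2.20 €), net profit = income − costs, and resource-use efficiencies.
* **Performance analysis** — full re-simulation sweeps over CO₂ setpoint and
  capacity, temperature shifts (±2 °C) and lighting hours (±3 h/day), a
  per-week marginal-lighting analysis (+2 h in one week at a time), a
  coordinate-ascent weekly-lighting-hours optimizer, and a windowed
  (35-day) drain-EC vs Brix correlation.

## Worked example

```r
library(tomatotwin)

truss_initiation_rate(c(19, 24))
#> [1] 1.10 1.47     # trusses/stem/week at the two temperature anchors

res <- run_season(run_config(preset = 306, seed = 1))
res
#> Season run, compartment 306 (seed 1): yield 13.72 kg/m2 over 46 harvest days
#> Season economics: yield 13.72 kg/m2, income 35.02 EUR/m2, costs 27.93 EUR/m2, net profit 7.09 EUR/m2
#>   costs: plants 3.30, electricity_peak 11.66, electricity_offpeak 0.81,
#>          heat 4.72, co2 0.81, labor 6.64, water_nutrients 0.00
#>   RUE: heat 41.3 MJ/kg, elec 12.1 kWh/kg, CO2 0.74 kg/kg, water 26.9 L/kg,
#>        nutrients 89.4 g/kg
```

`yield` is class-A fresh yield (kg/m²); `income` prices every harvested
truss by its Brix and calendar week; `net_profit` is income minus the
tariffed resource costs. The water efficiency (26.9 L/kg) uses net crop
uptake; nutrients follow the 1 EC ≈ 1 kg salts/m³ rule.

Comparing strategies:

```r
tab <- compare_presets(lapply(c(302, 303, 306), function(id)
  run_season(run_config(id, seed = 1))))
round(tab[, c("compartment", "yield", "income", "costs_total", "net_profit")], 2)
#>   compartment yield income costs_total net_profit
#> 3         306 13.72  35.02       27.93       7.09
#> 1         302 13.24  33.53       26.56       6.97
#> 2         303 13.99  35.57       29.71       5.86
```

The manually-grown reference archetype (303) produces well but pays for it
in heating and labor (its stem-density doubling to 8 stems/m² before
topping), ending last in net profit — the qualitative outcome the
experiment reported.

Sensitivity of net profit to the control strategy:

```r
w  <- generate_weather("2019-12-16", "2020-05-29", seed = 1)
sweep_lighting(302, deltas_h = c(-3, 0, 3), weather = w, seed = 1)
weekly_lighting_marginal(302, weather = w, seed = 1)   # Fig-22-style curve
optimize_weekly_lighting(302, weather = w, seed = 1)   # coordinate ascent
```

A command-line wrapper with the same operations ships in
`inst/cli/tomatotwin.R`
(`Rscript inst/cli/tomatotwin.R simulate --preset 306 --seed 1 --out out/`).

## Layout

```
R/                      implementation (weather, strategy, climate, crop,
                        economics, analysis, season orchestration, CLI)
src/climate_day.cpp     compiled 5-minute climate kernel
tests/testthat/         unit + property tests, test-acceptance.R
scripts/acceptance.R    acceptance report
vignettes/              methods vignette (model description & choices)
inst/extdata/           preset-calibration.csv (archetype levels)
```
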