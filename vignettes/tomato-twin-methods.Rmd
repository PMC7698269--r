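---
title: "A desk-scale greenhouse tomato twin: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A desk-scale greenhouse tomato twin: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tomatotwin)
```

This vignette is the package's own account of its science: what each model
component assumes, which parameters matter and why they have the defaults
they do, what the synthetic data emulate and do not, and where the design
was genuinely open. Everything quantitative claimed here is computed by the
test suite or the acceptance script; nothing is asserted that the code does
not itself verify.

## The problem being modelled

Six identical high-tech greenhouse compartments (96 m² floor, HPS + LED
supplemental lighting, two screens, rail and crop-pipe heating, roof
ventilation, fogging and CO₂ supply) grow an indeterminate cherry tomato
from mid-December to the end of May. Each compartment follows a different
open-loop control strategy: setpoint schedules for lamps, temperature,
CO₂, humidity and irrigation plus weekly crop-management instructions
(stem density, fruit pruning, topping date). The season is scored on net
profit: Brix- and season-dependent fruit price times class-A yield, minus
electricity (tariffed by the 07:00–23:00 clock), heat, tiered CO₂, labor
proportional to stems·days, and plant material. The package reproduces
this world at desk scale and then asks the counterfactual questions a
grower (or an autonomous controller) would ask: what happens to net profit
if I light longer, dose more CO₂, or run warmer?

## Synthetic weather

`generate_weather()` produces seeded 5-minute series of global radiation,
PAR, temperature, humidity and wind.

* Radiation is Haurwitz clear-sky irradiance from solar geometry at the
  site latitude (default 52° N), multiplied by `1 − 0.52·c` where the cloud
  cover `c ∈ (0,1)` is a logistic transform of a latent Gaussian AR(1)
  process. The default lag-one-day autocorrelation (`cloud_persistence =
  0.6`) and latent spread were chosen together so that (a) the all-sky to
  clear-sky ratio averages ≈ 0.75, a bright but plausible season for the
  Dutch coast, and (b) the season-mean daily integral varies by well under
  10% across seeds — a stability property the tests check over 22 seeds.
  Radiation is identically zero below the horizon and bounded by the
  clear-sky integral every day, by construction.
* Temperature is a seasonal cosine (≈ 2.5 °C in January to ≈ 14 °C in late
  May) plus a diurnal cycle peaking at 15:00 and a slow AR(1) anomaly;
  humidity and wind are independent bounded noise processes. There is no
  humidity–wind–radiation coupling beyond the deterministic terms: the twin
  only needs realistic forcing statistics, not reanalysis fidelity.
* The PAR conversion is linear at 1.0 µmol s⁻¹ per W of global radiation
  (≈ 47% PAR energy fraction × 2.1 µmol/J in-band).

The generator is calibrated only loosely (clear-sky bounds and plausible
means); it is **not** the 2019–2020 weather, and no conclusion that depends
on a specific historical weather event can be drawn from it.

## Strategies and presets

A schedule is a daily day/night template plus a per-week lamp-hours
profile, expanded lazily to 5-minute slots; the lamp block is centred on
solar noon and LED power is hard-coupled to HPS power. Day setpoints apply
when lamps are scheduled on or the sun is up. A late-season linear CO₂
setpoint taper (week 13 to the end, down to 450 ppm) mirrors how all teams
reduced CO₂ targets once ventilation made summer dosing futile.

The six presets are *archetypes*, not reconstructions: the published record
gives topping dates exactly (16–30 April) but team strategies only as
weekly aggregates. Preset levels were calibrated once (see
`inst/extdata/preset-calibration.csv`) so that

* each compartment's realized season-average indoor temperature lands
  within ≈ 0.2 °C of its published average (21.34–23.25 °C),
* the lighting shares order as reported (305 heaviest, 302/304 lightest),
* 301 doses the most CO₂, and 303 doubles stem density to 8 stems/m² just
  before topping,
* the fruits-per-truss targets follow from the published per-stem fruit and
  truss counts (their ratio implies ≈ 14–17 fruits per truss; 305 is
  treated as a split-truss strategy since its implied ratio reaches the
  single-truss cap).

Perturbation operators (`shift_temperature`, `adjust_lighting_hours`,
`adjust_co2`, `set_weekly_lighting_hours`) are the identity at zero
perturbation, touch only the fields they name, and enforce their stated
ranges *cumulatively* across repeated calls — a second +2 °C shift on an
already shifted schedule is rejected rather than silently compounding.

## Climate twin

One well-mixed air node per compartment (the analysis operates on
compartment averages), stepped at 300 s:

* **Energy**: solar gain (70% of transmitted global becomes sensible heat),
  full lamp electrical power as heat, proportional heating toward the
  heating line (gain 30 W/m²/K, capped at the 180 + 30 W/m² pipe
  capacities, with minimum-pipe setpoints acting as heat-power floors), an
  envelope loss of 6.5 W/m²/K modified by screens, and ventilation
  exchange from a proportional controller (4 °C P-band above the
  ventilation line). The published record describes setpoints, not
  controller gains; the gains are configurable with these documented
  defaults.
* **CO₂**: proportional dosing toward the setpoint over a 50 ppm band
  (daytime only), ventilation loss toward 410 ppm outside, and crop
  exchange (gross assimilation minus dark respiration).
* **Humidity**: transpiration and fogging sources, ventilation and
  cover-condensation sinks, fogging controlled toward the
  humidity-deficit setpoint.

Numerics: sources and controls are evaluated at the incoming state and the
exchange terms implicitly, so the scheme is unconditionally stable at the
5-minute step *and* the CO₂/water ledgers close exactly — conservation is
structural, not approximate, and the tests assert closure at machine
precision. The kernel is compiled (Rcpp) for speed; a scalar R
implementation (`step_climate()`) is kept as an independent oracle and the
two are compared slot-by-slot in the tests. A passive greenhouse converges
to the closed-form steady state of the linear balance, which the tests use
as an analytic oracle.

Lamp electrical efficacies (HPS 2.1, LED 3.0 µmol/J) are not published for
these fixtures; they set the electricity bill and therefore the economics
of the lighting sweeps, and are exposed in `greenhouse_params()`.

## Crop twin

An hourly-to-daily source–sink model:

* **Source**: canopy gross photosynthesis per 5-minute slot, summed to the
  daily total — Beer-law interception over LAI (k = 0.7), a rectangular
  hyperbola in absorbed PAR whose asymptote saturates in CO₂ (Km = 300
  ppm) and is flat within ~5% over 18–24 °C. Maintenance respiration is
  Q10 = 2 on both biomass pools; the net is partitioned.
* **Sinks**: each truss demands potential growth proportional to its fruit
  count and a normalised age curve, faded out as fruits approach a genetic
  size cap (1.25 g DM ≈ 13.9 g fresh); the vegetative pool demands a
  per-stem potential. Partitioning is proportional to these potentials,
  total growth is capped at their sum, and surplus assimilate is
  discarded. This single mechanism produces the three regimes the season
  analysis turns on: a sink-limited juvenile phase (extra light buys
  nothing), a source-limited adult crop (extra light buys yield), and a
  sink-starved post-topping tail (extra light again buys nothing).
* **Development**: stems initiate trusses at `1.1 + 0.074·(T − 19)`
  trusses/week (the two published anchors, 1.1 @ 19 °C and 1.47 @ 24 °C),
  after a juvenile delay of 0.735 weeks fitted once by inverting
  `trusses/stem = rate(T)·(weeks − delay)` on the compartment-301 record
  (21.34 °C, topped 30 April, 23.8 trusses/stem). The delay is implemented
  as calendar time: at the constant temperatures used for calibration a
  thermal and a calendar delay are indistinguishable, and calendar time
  keeps the closed form exact.
* **Ripening**: physiological fruit age accumulates as the temperature sum
  above 4 °C; a truss is harvested when it passes 810 °C·d (≈ 46 days at
  21.5 °C). The measured fruit growth period in the experiment was ≈ 55
  days from *visible fruit growth*, which starts after truss initiation;
  the shorter initiation-to-harvest sum is what makes the early-topped
  compartments finish their last trusses by 29 May while the late-topped
  ones (301, 304) carry unharvested plant load to the end — both observed
  behaviours.
* Fruit pruning trims each new truss to the plan target, hard-capped at
  16 (single) / 20 (split); leaf pruning is folded into an LAI ceiling of
  3.5 with biomass above the ceiling leaving the crop.

## Quality and economics

Brix per harvest record is the cultivar base 8.7 plus a dry-matter
deviation term, a bounded per-preset modifier (305 highest, 303 lowest,
all within ±0.8 °Brix) and seeded noise (sd 0.3). Drain EC is deliberately
**not** an input: no EC–Brix effect exists for this cultivar, and the
package's own windowed EC–Brix analysis is expected to find |r| < 0.3 on
simulated seasons while recovering r > 0.99 when a synthetic link is
injected — both are acceptance tests. The flavor score is a logistic
surrogate that preserves only the monotone Brix–flavor association; the
laboratory flavor model itself takes lab measurements and is out of scope.

Prices: a weekly base declining from 3.62 €/kg by 0.069 €/kg per week
(winter scarcity to summer glut) plus 0.15 €/kg per °Brix above 8.7,
floored at 1.20 €/kg. The published curve is not numerically printed; this
calibration was chosen once so that the six preset incomes fall inside the
published 33.00–37.22 €/m² envelope, and then frozen. Costs apply the
published tariffs verbatim. Water and nutrient unit prices were not
published and default to zero.

Two published ambiguities are resolved as follows and not revisited:
the printed per-compartment income/cost/profit columns do not satisfy
income − costs = profit, so the package implements the stated definition
(`net_profit = income − Σcosts`, an exact identity in the tests) rather
than reverse-engineering hidden cost terms; and the stated "L supplied per
kg" water efficiency is only consistent in magnitude with *net uptake*
(~25–28 L/kg), so net uptake is used and the ambiguity flagged here.

## Sensitivity analysis and the lighting optimizer

All sweeps re-simulate the full season per grid point on one fixed weather
realisation (the real analysis had exactly one realised season), so the
zero-perturbation point reproduces the baseline bit for bit. The
acceptance tests assert the published orderings: the net-profit response
to ±3 h of lighting exceeds the CO₂ and temperature responses for every
preset; the lowest CO₂ setpoints lose money while extra dosing buys
little; and the per-week marginal value of +2 h lighting is negative in
the juvenile weeks, peaks in mid-season and collapses toward the end as
sunlight rises and prices fall. The weekly optimizer is cyclic coordinate
ascent (±1 h/day per move within 0–20 h, accept only improvements) — the
published account names only the stopping condition ("until the computed
net profit showed a maximum"), so the simplest monotone ascent was chosen;
its objective trace is non-decreasing by construction.

Interactions between light, temperature and CO₂ are deliberately not
co-optimized, mirroring the scope of the original analysis.

## What a green test does and does not establish

The synthetic season reproduces the *structure* of the experiment — its
calendar, equipment limits, control vocabulary, price logic and the
published calibration envelopes (yield 12.9–14.4 kg/m², income
33.00–37.22 €/m², plant load ≤ 800 fruits/m², mean Brix 8.7, fruit dry
matter 9.0%) — under one stated synthetic weather realisation. It does
not reproduce the teams' AI controllers, the real 2019–2020 weather, or
per-compartment resource-use tables: heat use in particular is
over-predicted relative to the best real compartments (no humidity-based
ventilation-minimisation tricks are modelled), and the net-profit *ranking*
of the archetypes is therefore not a prediction. The reference model's own
known bias is inherited deliberately: the post-topping yield boost from
accelerated ripening after apex removal is not modelled, and no parameter
was tuned to hide that.

## Known limitations

* Single air node: no vertical gradients, screen-gap control or per-lamp
  light maps.
* Open-loop strategies only; the feedback loops live in the climate
  controllers, not in the strategies.
* Fruit quality beyond Brix (acidity, firmness, juice fraction) is out of
  scope, as are pests, diseases and labor beyond the stems·days rule.
* The preset quantitative levels are calibrated archetypes; slot-level
  team setpoints were never published.
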