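Package: tomatotwin
Title: Greenhouse Cherry-Tomato Digital Twin and Techno-Economic Analysis
Version: 0.2.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale digital twin of a supplementally lit Dutch greenhouse
    compartment growing an indeterminate cherry-tomato crop over a December to
    May season. Couples a seeded synthetic-weather generator, an open-loop
    setpoint-schedule vocabulary with six archetype control strategies, a
    lumped greenhouse energy/CO2/humidity balance, and a source-sink crop model
    with per-truss fruit bookkeeping (temperature-driven truss initiation,
    physiological-age ripening, pruning and topping). Scores each season by
    yield, fruit quality (Brix), resource-use efficiency and net profit at
    published tariffs, and provides sensitivity sweeps over CO2, temperature
    and supplemental-lighting hours plus a coordinate-ascent weekly-lighting
    optimizer.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
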