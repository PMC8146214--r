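Package: pastureLCA
Title: Farm-Gate Carbon Footprint and Nitrogen Balance of Grazed Dairy Pastures
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Life-cycle model for rotationally grazed, irrigated dairy
    pastures under different nitrogen fertilization intensities. Converts
    per-treatment herbage yield, nitrogen yield and net-energy-for-lactation
    yield into potential energy-corrected milk output, computes field- and
    farm-gate nitrogen balances with ammonia, leaching and nitrous-oxide
    loss terms, assembles a per-hectare greenhouse-gas inventory (enteric
    methane, soil N2O via an exponential response to the field nitrogen
    balance, embodied inputs, irrigation, farm operations, manure storage
    and a soil-organic-carbon offset), and reports carbon and nitrogen
    footprints per kg of energy-corrected milk. Includes a synthetic
    scenario generator with a linear-plateau yield response for testing and
    parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
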