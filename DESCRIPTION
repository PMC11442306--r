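Package: borealfire
Title: Process-Based Simulation of Fire Weather, Burned Area, and Fire
    Carbon Emissions
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: A daily-timestep, gridded simulator of wildfire occurrence,
    elliptical fire spread, burned area, and fire carbon emissions for
    boreal and temperate landscapes.  Fire danger is driven by the
    Canadian Forest Fire Weather Index (FWI) system (FFMC, DMC, DC, ISI,
    BUI); fire occurrence is the product of biomass, ignition, and
    fuel-moisture conditional probabilities; spread rates are plant
    functional type specific functions of ISI and BUI; and carbon fluxes
    are computed from per-pool combustion and mortality fractions,
    including the soil pool.  Includes a seeded synthetic forcing
    generator with seasonal cycles, autocorrelated noise and secular
    trends, multiplicative and additive delta-method bias correction of
    lightning series, and factorial driver-attribution, sensitivity, and
    ensemble-significance experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
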