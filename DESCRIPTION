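Package: thermotraits
Title: Microbial Thermal Traits and Annual Soil Carbon Budgets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits the dual-kinetics extension of the Ratkowsky square-root
    model to temperature-screening assays of bacterial growth, fungal growth
    and soil respiration; derives community thermal trait indices (Tmin,
    Topt/Ttp, Tmax, Q10); reconstructs hourly soil temperature and moisture
    forcing from sparse afternoon field measurements with a symmetric
    diurnal sinusoid and a DAYCENT-type moisture rate modifier; integrates
    lab-derived temperature and moisture response functions into annual
    microbial growth, respiration and carbon-use-efficiency budgets per unit
    soil area; and decomposes climate-manipulation treatment effects into
    direct temperature, direct moisture, and thermal-trait adaptation
    components via counterfactual scenarios. Includes a synthetic-data
    generator emulating both assay and field inputs so the full pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
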