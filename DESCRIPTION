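Package: atmort
Title: Age Trajectories of Child Mortality from Count Tables, Hazard Models,
    and Congenital-Risk Frailty Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the age-associated decrease in child mortality
    from tabulated death and living-population counts on the WHO age grid.
    Aggregates counts over countries and calendar years (the Halley method),
    builds age trajectories of mortality (ATM) as deaths per person-year,
    and fits and tests a family of hazard models on the log-log scale: the
    quadratic linearity check, the two-parameter linear model, the
    one-parameter inverse-proportion model with its closed-form estimator and
    nested F-test, a bending frailty-mixture hazard, and four historical
    childhood-mortality models (exponential, Bourgeois-Pichat,
    Heligman-Pollard childhood term, Weibull). A frailty-population simulator
    generates WHO-style count tables from cohorts with heterogeneous
    congenital risk, together with deterministic expected-count oracles, so
    every pipeline stage is testable without external mortality databases.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
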