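Package: segsim
Title: Microsimulation of Occupational Segregation and Hypertension in the
    Healthcare Workforce
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Individual-level state-transition microsimulation of hypertension
    development among Black and white healthcare workers in four occupational
    classes, driven by logistic risk equations on body mass index, smoking,
    family history, employment and the psychosocial work environment (job
    demand, control and support).  Includes a provenance-tagged parameter
    registry with constant-hazard (DEALE) probability conversion, synthetic
    parameter fixtures, seed-reproducible cohort initialisation, a
    counterfactual occupational-desegregation scenario engine with common
    random numbers, one-way (+/- 25 percent) sensitivity analysis, and
    reporting of prevalence trajectories, age-group summaries, racial gaps
    and cost-savings estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
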