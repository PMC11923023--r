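Package: mitecomp
Title: Stage-Structured Competition of Defence-Inducing and
    Defence-Suppressing Spider Mites Under Temperature Regimes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing competition between plant-defence-inducing
    and defence-suppressing spider mite strains sharing a tomato host.
    Provides mortality-corrected per-capita assay metrics (daily female
    survival, fecundity per alive female, feeding damage per female),
    derivation of demographic rates (development, stage-specific mortality,
    sex-ratio-corrected net reproduction) from leaf-disc and leaflet
    observations, a two-phenotype stage-structured ODE competition model
    with shared-capacity density dependence and a cross-strain benefit to
    inducers, piecewise-constant temperature schedules (constant and
    repeating-heatwave scenarios), an event-detecting simulator (strain
    crossover, end-of-season persistence), and a synthetic-data generator
    for end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
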