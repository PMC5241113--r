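Package: forestchron
Title: Dating Regeneration Halts in Tropical Tree Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Demographic reading of forest-inventory diameter structures
    for light-demanding tropical trees: diameter-class matrices and
    composition summaries, correspondence analysis and clustering of
    genus-level diameter distributions, truncated-Weibull estimation of
    modal diameters, fitting and BIC comparison of diameter-growth models,
    age and calendar-date estimation from growth trajectories (mean
    annual increment or growth-model ODEs), and radiocarbon calibration
    with summed probability distributions. Includes a forward simulator of
    cohort communities (recruitment epochs, annual mortality, growth
    noise) so that every stage of the inference chain can be validated on
    data with known history.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    graphics,
    stats,
    utils,
    yaml
Suggests:
    fitdistrplus,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
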