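Package: poprecover
Title: Stochastic Recovery of Stage-Structured Populations After an
    Environmental Disaster
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonautonomous stage-structured matrix projection models for
    populations recovering from a single environmental disaster. Vital
    rates (stage survivorship, stage transition, fecundity) are reduced
    by a time course that follows either a sigmoid continuous recovery
    function or a step recovery function, and demographic stochasticity
    is simulated at the individual level with multinomial fate draws and
    binomial births. Monte-Carlo endpoints include the probability of
    recovery to the pre-event abundance within a horizon and the mean
    first-passage recovery time. The Gulf-of-Mexico sperm whale
    parameterization ships as the packaged reference case.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    grDevices,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
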