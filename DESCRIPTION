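Package: sporemem
Title: Kinetic Network Model of Memory in Bacterial Spore Germination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic kinetic model of nutrient-triggered germination of
    Bacillus subtilis spores, built around a five-state molecular network:
    germinant receptors in inactive and active states, and SpoVA channels in
    closed, activated-closed and open states with cooperative (Hill) positive
    feedback on channel opening. Provides single-spore trajectory integration
    under piecewise-constant germinant pulse protocols with germination
    threshold detection, population ensembles with gamma-distributed receptor
    copy numbers, cumulative percentage-germination curves, deterministic
    receptor copy-number scans, closed-form analytic reductions of the
    network, bistable switch fixed-point analysis, inner-membrane geometry
    calculators, and configuration/serialization tooling for reproducible
    double-pulse memory simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    fitdistrplus,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
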