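Package: fermsens
Title: Inverse-System Soft Sensing for Fed-Batch Pichia pastoris Fermentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Grey-box kinetic modelling and inverse-system soft sensing for
    fed-batch Pichia pastoris fermentation. Provides a six-state ordinary
    differential equation simulator of the process (biomass, methanol,
    inulinase, dissolved oxygen, hydrogen-ion concentration, broth volume)
    with pluggable specific-rate laws, a numerical Jacobian-rank diagnostic
    for local invertibility of the measurable-output map, signal
    preprocessing (spike-suppressing moving-average filter, five-point
    numerical differentiation, normalisation, local least-squares alignment
    of offline assays), a from-scratch fully connected network trained with
    the Adam optimizer, and a soft sensor that reconstructs the unmeasurable
    states (cell, substrate and enzyme concentration) from measurable
    signals (dissolved oxygen, pH, volume, feed rates, environment).
    Includes a seeded synthetic-campaign generator emulating a 240-hour
    methanol-induction phase with realistic sensor noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
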