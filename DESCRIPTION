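Package: redoxferm
Title: Kinetic Simulation of Redox-Regulated Fermentation in Escherichia coli
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A kinetic model of Escherichia coli central carbon metabolism
    with oxygen-dependent redox regulation. Transcription factors Fnr and
    ArcA scale enzyme maximal rates as Hill functions of cytoplasmic oxygen
    and of the oxidized quinone pool, coupling the respiratory chain (Nuo,
    Ndh, Cyo, Cyd) and the fermentative pathways (lactate, ethanol, acetate,
    formate, succinate) to the dissolved-oxygen level of a batch culture.
    The package integrates the batch fermentation ODE system with event
    detection for glucose depletion, simulates gene-knockout strains
    (fnr, arcA, pfl), sweeps dissolved-oxygen setpoints, and scans
    aerobic-to-microaerobic switching times for dual-phase lactate
    production (yield and productivity).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
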