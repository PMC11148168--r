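Package: oxymida
Title: Pericellular Oxygen Modelling and Deuterium-Water MIDA for Cell
    Culture Metabolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying two linked aspects of cell-culture
    metabolism. A steady-state Fick's-law diffusion-consumption model of
    the medium column predicts pericellular oxygen concentration, the
    maximum oxygen consumption rate a monolayer can sustain, and the
    maximum medium depth compatible with a demanded respiration rate,
    from plate geometry and medium volume. A mass isotopomer distribution
    analysis (MIDA) estimator infers fractional de novo lipogenesis (f),
    precursor deuterium enrichment (p) and the number of exchangeable
    hydrogen sites (N) of fatty acids from GC-MS isotopologue envelopes
    measured under deuterated-water labelling, via exact natural-abundance
    convolution and bounded nonlinear least squares. Extracellular
    glucose/lactate flux arithmetic and seeded synthetic-data generators
    for every input format are included so the full pipeline is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
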