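Package: quenchfit
Title: Fluorescence Quenching Titration Analysis for Protein-Nanoparticle
    Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of fluorescence quenching titrations of a protein by
    a nanoparticle quencher: Stern-Volmer fitting with quenching-rate
    constants and dynamic/static mechanism classification, double-logarithm
    and Hill-plot binding analysis with cooperativity calls, nonlinear Hill
    saturation fits, and van't Hoff thermodynamics with Gibbs free energies
    and dominant-force classification.  Includes a seeded synthetic
    titration generator so that every stage of the pipeline can be
    validated against known ground truth, CSV input, a JSON report writer,
    and base-graphics diagnostic plots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
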