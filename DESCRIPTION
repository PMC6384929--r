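Package: quenchfit
Title: Fluorescence Quenching Titration Analysis for Membrane Protein Orientation
Version: 0.1.0
Authors@R: person("quenchfit", "maintainers", email = "maintainers@quenchfit.org", role = c("aut", "cre"))
Description: Analysis pipeline for fluorescence quenching titration (FQT)
    assays that determine the orientation of fluorophore-labeled
    transmembrane proteins reconstituted in lipid vesicles. Calibrates the
    Stern-Volmer quenching constant from quencher-only titrations, fits the
    protected (quencher-inaccessible) fraction under a two-population
    fractional-accessibility model with the calibrated constant held fixed,
    aggregates replicate titrations, classifies orientation preference, and
    compares experimental conditions. Includes a seeded synthetic-titration
    generator with multiplicative log-normal intensity noise, bootstrap
    confidence intervals, joint-fit identifiability diagnostics, and a
    command-line interface for simulate/calibrate/fit/study workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
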