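Package: arraysense
Title: Bayesian Decoding and Information-Based Design of Cross-Specific
    Receptor Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Physical model of a cross-specific (combinatorial) receptor
    array in which ligands bind competitively and activate reporters with
    ligand-specific efficacies. Provides Bayesian inference by nested
    sampling to calibrate receptor-ligand binding free energies and
    efficacies from dilution-series reporter data, to decode absolute
    concentrations of every ligand in an unknown mixture from the joint
    array readout, and a Fisher-information (Hessian) engine that
    forecasts concentration uncertainties, optimizes receptor binding
    energies and efficacies by D-optimal design, and establishes the
    array's mixture-discrimination capacity. Includes seeded synthetic
    data generators for calibration curves, mixture response datasets and
    design studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
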