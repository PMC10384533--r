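Package: bayfate
Title: Tidal Hydrodynamics, PAH Fate and Transport, and Cancer-Risk Mapping for Semi-Closed Narrow Bays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A depth-averaged (2D) tidal shallow-water solver with
    alternating-direction-implicit time stepping, coupled to a multiphase
    fate-and-transport model for total polycyclic aromatic hydrocarbons
    (air-sea two-film exchange, sediment-water exchange, degradation and
    Stokes deposition), on an idealized semi-closed narrow bay. Includes
    Willmott-skill model validation, coordinate-descent parameter
    calibration, dynamic-equilibrium detection, and benzo[a]pyrene
    toxic-equivalent incremental lifetime cancer risk (ILCR) mapping by
    ingestion and dermal pathways.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
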