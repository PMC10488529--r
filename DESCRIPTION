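Package: vetera
Title: Tiered Environmental Risk Assessment of Veterinary Medicinal Products
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements the EMEA/CVMP tiered environmental risk assessment
    (ERA) workflow for veterinary medicinal products spread to land via
    manure: Phase I total-residue soil exposure under the 170 kg N/ha
    nitrogen ceiling, Phase II Tier A groundwater, surface-water and
    sediment concentrations by Koc-based equilibrium partitioning,
    predicted no-effect concentrations by the assessment-factor and
    partition-equilibrium methods, and the PEC/PNEC risk-quotient decision
    tree with refinement hooks. Also provides the linear-calibration
    arithmetic used to confront predictions with measured surface-water
    concentrations: ordinary least squares fits, residual-based limits of
    detection and quantification (3.3 sigma/slope, 10 sigma/slope),
    relative standard deviation checks and back-calculated sample
    concentrations. Ships the complete penicillin G worked example
    (piglets, chickens, turkeys) as a fixture bundle and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
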