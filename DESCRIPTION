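Package: aneuflow
Title: Degradation-Aware Aneurysm Wall Mechanics and Hemodynamic Shear Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how degradation (damage-induced softening) of
    aneurysmal wall tissue interacts with intra-aneurysm hemodynamics. Implements
    a fiber-reinforced hyperelastic material model with saturating, irreversible
    damage and Mullins-type stress softening; a quasi-static thin-walled
    (membrane) tube surrogate for compliant-vessel inflation under cyclic
    pressure; three-element Windkessel outlet boundary-condition construction,
    integration and tuning against target systolic/diastolic/mean pressures; the
    wall-shear-stress metric stack (TAWSS, OSI, ECAP) on triangulated surface
    meshes; a comparison layer for paired non-degraded/degraded conditions
    (relative changes, correlation product, digitization, low/high shear regime
    classification); and a seeded synthetic-data generator that emulates
    fluid-structure-interaction output with known ground truth for recovery
    testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite,
    rlang,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    dplyr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
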