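Package: fibrilkit
Title: Quantitative Ultrastructure Analysis of Beaded Microfibrils
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for quantifying the ultrastructure of beaded
    extracellular-matrix microfibrils from electron micrographs: filament
    tracing and straightening, bead-to-bead periodicity measurement with
    group comparison by one-way analysis of variance with Dunnett
    contrasts, repeat extraction with translational alignment and axial
    stain-exclusion profiling, scanning transmission electron microscopy
    (STEM) dark-field mass-per-unit-length calibration against a tobacco
    mosaic virus standard, rotational symmetry-correlation analysis of 3D
    density maps with density-threshold mass estimation, subparticle
    recentering of single-particle metadata, and one-site equilibrium
    binding analysis.  A ground-truthed synthetic-data generator renders
    beaded filaments, annular dark-field fields, symmetric volumes and
    particle tables so that every analysis stage can be validated by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    Matrix,
    stats,
    tiff,
    utils
Suggests:
    multcomp,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
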