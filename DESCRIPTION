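Package: nmrdyn
Title: Protein Dynamics and Compactness from Solution NMR
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis of protein conformational dynamics and hydrodynamic
    compactness from solution-state NMR observables: exponential fitting of
    longitudinal (R1) and rotating-frame (R1rho) relaxation decays with
    heteronuclear NOE, Lipari-Szabo model-free analysis of backbone amide
    15N relaxation (order parameters S2, internal correlation times, global
    rotational correlation time), global two-field Carver-Richards fitting
    of 15N CPMG relaxation dispersion with a Bloch-McConnell numerical
    oracle, pulsed-field-gradient stimulated-echo diffusion analysis with
    internal-reference hydrodynamic radii and Stokes-Einstein conversion,
    chemical shift perturbation titrations with single-site Kd fits and
    cumulative shift differences, box-sum peak quantification of gridded 2D
    spectral planes, and radii of gyration from PDB coordinates. Includes a
    synthetic-data generator with known ground truth for every observable,
    so the full pipeline is testable without spectrometer data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    minpack.lm,
    bio3d,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
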