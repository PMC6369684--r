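Package: gpatlas
Title: Probability Atlas of Atrioventricular-Dissociating Ganglionated
    Plexus Sites on the Left Atrium
Version: 1.0.0
Authors@R:
    person("GP Atlas", "Developers", email = "gpatlas@example.org",
           role = c("aut", "cre"))
Description: Tools for localising atrioventricular-dissociating
    ganglionated plexus (AVD-GP) sites from endocardial high-frequency
    stimulation (HFS) studies of the left atrium. Classifies R-wave time
    series around an HFS application into asystole, bradycardia or
    negative responses; calibrates the asystole ratio threshold from
    baseline atrial-fibrillation RR variability via a log-normal tail
    quantile; represents labelled triangulated left-atrial surface meshes
    and generates circumferential landmark rings at the pulmonary-vein
    junctions; coregisters patient geometries onto a reference shell with
    similarity (Procrustes) plus thin-plate-spline registration and
    angle-based fiducial selection scored by held-out target registration
    error; builds Gaussian-kernel probability atlases of AVD-GP sites
    across patients with peak detection and an area-concentration
    statistic; and simulates complete synthetic cohorts (atrial shells,
    deformations, HFS site layouts, R-wave series) for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
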