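Package: kvdosim
Title: Kilovoltage X-Ray Dosimetry for Preclinical Bone-Dose Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Dosimetric characterization of low-energy (80 kV) X-ray
    irradiation of layered bone and soft-tissue geometries, as used in
    preclinical radiological-burn models.  Provides embedded photon
    interaction coefficient tables with log-log interpolation, a
    semi-empirical filtered tungsten-anode spectrum model with air-kerma
    and half-value-layer computation, spectrum-weighted tissue-to-air
    kerma ratios and bone-composition sensitivity scans, a Monte Carlo
    photon and secondary-electron transport engine for slab and voxel
    phantoms (Klein-Nishina Compton sampling, photoelectric absorption
    with K-shell relaxation, continuous-slowing-down electron transport),
    beam-profile simulation and penumbra metrics with IAEA-style profile
    comparison, radiochromic-film calibration, and additive-dose EPR bone
    dosimetry with cohort variability statistics.  Seeded synthetic-data
    generators emulate every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
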