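Package: vaudit
Title: Virtual Dosimetry Audit for IMRT Credentialing
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for remote ("virtual") dosimetry audits used in
    intensity-modulated radiotherapy (IMRT) clinical-trial credentialing.
    Implements a radiochromic-film pipeline (red-channel optical density,
    unset-film non-uniformity correction, constrained polynomial calibration
    from subfilms, fiducial-mark registration to the plan isocenter), a
    detector-array pipeline (ArcCHECK helical cylinder unwrapping, Delta4
    orthogonal planes), a global gamma-index engine with credentialing
    presets (3%/3 mm and 3%/2 mm) plus an exhaustive brute-force oracle,
    minimal DICOM-RT Dose/Plan reading, pass/fail audit reports, and a fully
    seeded synthetic-data generator (C-shaped target dose fields, composite
    film scans, measurement exports) with plantable delivery errors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    stats,
    tiff,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
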