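Package: corvistk
Title: Corneal Deformation Analysis for Air-Puff Tonometer Image Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of Scheimpflug image sequences recorded by air-puff
    (Corvis-type) tonometers. Detects the outer and inner corneal contours in
    every frame by per-column brightness-gradient maxima with sub-pixel
    refinement, decomposes the resulting deformation field into a static
    baseline, a whole-eye (eyeball) response, a corneal deformation and a
    high-frequency (>100 Hz) vibration component via temporal FFT filtering,
    and computes the standard biomechanical parameters (applanation times,
    lengths and velocities, highest-concavity time, peak distance, radius of
    the concave arc, deformation amplitudes, corneal length changes, vibration
    metrics, scleral asymmetry) in pixel/frame units and calibrated physical
    units. A synthetic Scheimpflug sequence generator with exact ground truth
    makes every stage testable without patient data, and a command-line
    interface ties the pipeline together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    png,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
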