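Package: vtasteer
Title: Steering Accuracy and Energy Efficiency of Directional Deep Brain
    Stimulation Paradigms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation toolkit comparing two radial current-steering
    paradigms for directional deep brain stimulation leads: Multiple
    Independent Current Control (MICC), which sums simultaneously delivered
    stimulation fields, and Interleaving/Multi-Stim-Set (MSS), which
    alternates single-electrode pulse trains so fields act independently.
    Provides a segmented-lead geometry model, an analytic point-source field
    engine, an activating-function surrogate for axonal activation that
    builds binary volumes of tissue activated (VTAs) on a perpendicular axon
    lattice, amplitude titration to target VTA radii, steering metrics
    (equal-area bisector rotation angle, radius, volume, overlap), an
    implantable pulse generator battery current-draw model for MICC,
    Interleaving/MSS and coactivation, and a structured synthetic stand-in
    for a clinical directional-electrode impedance dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    nortest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
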