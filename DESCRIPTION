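Package: rapidcamp
Title: Kinetic Campimetry Simulation for Central Visual Field Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Deterministic simulation engine for rapid kinetic campimetry, a
    tangent-screen screening test for absolute scotomas in the central 10
    degree visual field. Provides the screen geometry (separable tangent
    projection between visual-field degrees and screen centimetres/pixels),
    an eccentricity-dependent stimulus size law, the screening trajectory
    with trapezoid coverage-area accounting, parametric synthetic visual
    fields (blind spot, arcuate nerve-fibre-bundle and quadrant scotomas
    with absolute or relative depth), a simulated psychophysical observer,
    off/on scotoma-event reconstruction and slow kinetic boundary
    delineation, and a geometric proxy of a 68-point 10-2 static perimetry
    exam for method comparison on the same ground truth.
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
    withr,
    xml2
Config/testthat/edition: 3
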