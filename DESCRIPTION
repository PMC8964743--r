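Package: lltefoot
Title: Lower Leg Trajectory Error Design Framework for Passive Prosthetic Feet
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Design and evaluation of passive energy-storage-and-return
    prosthetic feet with the lower leg trajectory error (LLTE) framework.
    Provides a wide-Bezier parametric compliant foot model, a corotational
    plane-frame finite element solver for quasi-static large deflections,
    stance-phase contact kinematics that resolve the lower leg pose from
    ground reaction forces, centre of pressure and knee moment, the LLTE
    objective, and genetic-algorithm shape optimization under stress and
    geometric constraints.  A companion gait-analysis layer computes the
    standard biomechanical evaluation metrics (stance detection, symmetry
    index, Froude number, roll-over shape radius, effective foot length
    ratio, unified-deformable foot power and energy return, centre-of-mass
    step-to-step transition work, trajectory deviation scores) on marker
    plus force-plate step recordings, with synthetic generators for both
    the reference gait and full step recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
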