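Package: atnav
Title: Semi-Automated Navigation for Array Tomography Serial-Section Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for navigating ribbons of serial ultrathin sections in
    array tomography and correlative light/electron microscopy. Builds a
    stitched brightfield overview of the coverslip, detects trapezoidal
    sections with a quadrilateral active contour, propagates regions of
    interest between differently shaped sections through a bilinear
    isoparametric (transfinite) mapping, interpolates a focus surface with
    Sibson natural-neighbour interpolation, generates resumable stage
    navigation plans across a magnification ladder, and refines stage
    targets by feeding phase-correlation stack registration back into the
    plan. Includes a fully seeded synthetic ribbon generator and simulated
    microscope used as the test harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    yaml,
    tiff,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
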