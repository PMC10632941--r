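Package: lamellaR
Title: Automated Lamellar Thickness Measurement in Polarized-Light
    Micrographs of Cortical Bone
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Measures the average thickness of bright and dark bone
    lamellae from operator-annotated polarized-light micrographs.  An
    annotated image carries a yellow rectangle around the measurement
    area with red fiducial pixels on its top corners and green on its
    bottom corners; the pipeline detects the fiducials, rotates the
    image so the lamellae run horizontally, crops to the rectangle
    interior, binarizes each pixel against the mean of the nearest
    pixels in its column, repairs isolated wrong-color pixel runs,
    run-length encodes every column, rejects columns whose first-pixel
    color or lamella counts disagree with operator expectations, and
    averages each lamella's pixel thickness across retained columns
    before converting to micrometers.  Includes a synthetic annotated
    micrograph generator with ground truth for validation, and exact
    paired sign-test utilities for method-agreement analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
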