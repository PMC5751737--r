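Package: MangoSizer
Title: On-Tree Mango Fruit Sizing from Night RGB-D Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detection and millimetre-scale sizing of un-occluded mango
    fruit in night-time RGB-D canopy images. Implements depth-to-colour
    registration and field-of-view cropping from camera intrinsics, a
    HOG-feature cascade detector built from boosted decision stumps,
    Otsu plus CIE L*a*b* chroma segmentation with area morphology, a 1D
    run-length stalk filter, a moment-ellipse completeness gate, thin-lens
    conversion of pixel extents to millimetres, allometric fruit mass
    estimation, and a synthetic RGB-D canopy scene generator with ground
    truth so every stage is testable without orchard data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    EBImage,
    png,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
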