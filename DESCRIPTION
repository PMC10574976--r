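Package: thermobrace
Title: Infrared Thermography Assessment of Scoliosis Brace Pressure
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Decides, from a paired RGB/thermal image of a patient's back
    taken immediately after brace removal, whether a scoliosis brace exerted
    adequate pressure. An operator-supplied region of interest over the
    prescribed thrust area is mirrored across the backbone axis, both
    regions are mapped onto the thermal grid, jointly normalised to
    grayscale, partitioned into subregions, and the two vectors of
    subregion means are compared with a pooled-variance Student's t-test;
    a thermally elevated, statistically significant thrust region is
    classified as adequate pressure. The package also implements the full
    performance-evaluation machinery (balanced subset construction,
    leave-one-out cross-validation with threshold grid search, type-A
    uncertainty and first-order propagation with a coverage factor) and a
    synthetic thermal-phantom generator emulating a 160x120, 100 mK
    smartphone-attached thermal camera, so the whole pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    png,
    tiff,
    jpeg,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
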