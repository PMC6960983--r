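Package: grainstereo
Title: Stereo Photogrammetric Extraction of Grain Thickness from Edge
    Shape Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Measures the thickness of rice and similar grains from a
    two-camera stereo pair without relying on surface texture. Grains are
    segmented from images of a circle-grid calibration board, corresponding
    grains and edge points are matched across the pair using polar-distance
    shape profiles with circular correlation, edge heights are reconstructed
    by photogrammetric space intersection, and thickness is reported as twice
    the mean edge height over a population of randomly flipped grains. A
    synthetic stereo-scene generator with exact ground truth makes the whole
    pipeline testable without real imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
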