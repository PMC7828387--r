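Package: vesicleflow
Title: Whole-Cell Vesicle Transport Direction Analysis from Fluorescence
    Time-Lapse Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Dense Lucas-Kanade optical flow analysis of single-channel
    fluorescence time-lapse image stacks, aimed at visualizing intracellular
    vesicle transport at the whole-cell level.  The geometric cell center is
    estimated from the per-pixel temporal intensity standard deviation; each
    flow vector is classified as moving inward (toward the center, the
    direction of endocytosis) or outward by comparing its four-quadrant angle
    with the angle of the pixel-to-center vector; results are summarized over
    time, resampled onto polar (R, theta) coordinates about the center, and
    rendered with a diverging red-blue colormap or a conventional HSV
    encoding.  A seeded synthetic vesicle-movie generator with per-frame
    ground truth makes every stage testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    tiff,
    png,
    yaml,
    jsonlite,
    EBImage,
    withr,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
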