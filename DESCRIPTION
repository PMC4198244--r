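Package: camochange
Title: Quantifying Rapid Colour Change and Camouflage Through Predator Vision
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An image-analysis pipeline for quantifying rapid colour change
    and background matching in small fish as seen by an avian predator.
    Covers calibrated multispectral imaging (linearization against grey
    reflectance standards and equalization to an in-frame 40% standard),
    polynomial mapping from camera channels to tetrachromatic cone catches
    including the double cone, tetrahedral colour-space metrics (saturation,
    opponent hue ratios, double-cone luminance), receptor-noise-limited
    chromatic and achromatic discrimination (just-noticeable differences),
    and the planned-comparison statistics used to test background matching
    over time. Ships a synthetic-scene generator so the full chain runs
    end to end without external imagery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    tiff,
    png,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
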