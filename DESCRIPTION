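Package: thermotex
Title: Texture Analysis of Equine Thermal Images Across Rider Bodyweight Groups
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: ROI-based extraction of conventional thermal features and 31
    texture features (first-order histogram statistics, gray-level run-length
    matrix, gray-level co-occurrence matrix) from RGB-decomposed pseudo-color
    thermal images, together with the two-stage significance screen used to
    compare rider:horse bodyweight-ratio groups before and after exercise.
    Includes a synthetic-study generator that emulates the pre/post imaging
    design so the full pipeline can be exercised without raw images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    ggplot2,
    optparse,
    withr
Config/testthat/edition: 3
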