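Package: dermoborder
Title: Skin Lesion Border Irregularity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated assessment of the border-irregularity (B) feature of the
    ABCD melanoma screening rule from dermoscopy-style lesion images. Segments
    the lesion with fuzzy c-means refined by a type-II fuzzy ambiguity
    threshold and gradual-focusing defuzzification, extracts the border with a
    four-step Canny detector, summarizes border roughness with a 27-value
    descriptor (box-counting fractal dimension, convexity, and 25 Zernike
    moment magnitudes), and classifies borders as regular or irregular with a
    convolutional neural network / Gaussian naive Bayes probability ensemble.
    Includes a seeded synthetic-lesion generator so the full pipeline is
    testable without external image data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    tibble,
    dplyr,
    purrr,
    ggplot2,
    rlang,
    generics,
    jsonlite,
    readr,
    igraph,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    optparse,
    tiff
Config/testthat/edition: 3
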