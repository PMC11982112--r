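Package: underice
Title: Under-Ice Phytoplankton Imaging Campaigns, Classification and
    Mixing Diagnostics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing winter phytoplankton time series collected
    with an imaging-in-flow cytometer moored under lake ice. Generates
    synthetic grayscale ROI images and environmental profiles with known
    ground truth; segments images, extracts shape and texture features and
    estimates per-image biovolume by a distance-map solid-of-revolution
    method; assembles balanced random-forest training sets and selects a
    classifier over a grid of training-set sizes and tree counts with an
    explicit unclassified contract; computes freshwater density, thermal
    expansibility and a Richardson-number diagnosis of radiatively driven
    convective mixing below stable surface layers; grids profile time
    series onto fine time-depth sections; and aggregates classified images
    into per-taxon biovolume-per-mL series with verification-sample
    comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    knitr,
    png,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
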