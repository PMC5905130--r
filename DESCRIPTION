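Package: xoseed
Title: Fluorescent Seed Counting and Meiotic Crossover Frequency Estimation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Counts fluorescent Arabidopsis seeds in stereomicroscopy images
    and converts the seed-class tallies into meiotic crossover frequencies and
    genetic map distances. Seeds are detected in bright-field images with a
    trainable three-class random-forest pixel classifier (Seed / SeedEdge /
    Background), declumped by watershed segmentation, and classified as
    red-only, green-only, double- or non-fluorescent by adjustable per-object
    intensity thresholds in the RFP and GFP channels. Image-level quality
    control removes images with a skewed RedOnly:GreenOnly ratio before
    pooling. Pooled counts are fitted with the closed-form estimator for the
    two-dominant-marker coupling-phase F2 segregation model, giving the
    recombination fraction and Haldane/Kosambi map distances. Includes a
    synthetic image generator with ground truth for end-to-end validation,
    treatment-comparison statistics (normalization to control, Welch's t-test)
    and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    ranger,
    tiff,
    optparse,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
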