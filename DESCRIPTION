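Package: phasorFLIM
Title: Phasor-Based Fluorescence Lifetime and Second Harmonic Generation
    Image Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fit-free analysis of time-resolved multiphoton microscopy of
    tissue autofluorescence. Simulates time-correlated photon-count image
    stacks of tissue-like scenes (elastin and collagen fibers, NAD(P)H in
    cells, red blood cells, lipopigments) with Poisson noise and a Gaussian
    instrument response; transforms decay stacks to phasor space; calibrates
    against a mono-exponential reference of known lifetime; selects lifetime
    populations with circular phasor cursors and maps them back onto the
    intensity image; segments elastin and collagen fibers from intensity
    images and quantifies the elastin/collagen index (ECI), collagen
    percentage and integrated density per field of view; and compares paired
    healthy versus tumor frame metrics with an exact Wilcoxon signed-rank
    test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    pracma,
    stats,
    tiff,
    utils,
    grDevices,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
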