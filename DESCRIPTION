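Package: dotshape
Title: Dot-Boundary Shape Stimuli, Scan and Centroid Encodings, and
    Simulated Match-Recognition Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates closed dot-boundary shape stimuli on an LED-board style
    raster grid, encodes displays with two compact shape summaries (a trimmed,
    re-binned row-and-column projection histogram, and a normalized
    distribution of dot-to-centroid distances), builds all-pairs similarity
    scales, and simulates same/different match-recognition experiments with
    signal-detection (d-prime, p(c)max) and linear-regression analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
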