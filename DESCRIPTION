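Package: microvolt
Title: Resting-State EEG Microstate Segmentation and Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for resting-state EEG microstate analysis on low-density
    (10/20) recordings: global field power peak extraction, polarity-invariant
    (modified k-means) clustering of peak topographies into microstate
    templates, Krzanowski-Lai selection of the template number, topographic
    comparison of conditions by global map dissimilarity with a permutation
    TANOVA, winner-take-all backfitting with duration, occurrence, coverage
    and directional-predominance metrics, and aligned rank transform (ART)
    factorial ANOVA with ART-C contrasts for nonparametric repeated-measures
    group statistics. Includes a synthetic EEG generator with planted
    microstate structure for validation, readers for EDF and a plain
    delimited matrix format, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
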