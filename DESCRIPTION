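Package: reorientr
Title: Analysis of Hippocampal Place-Cell Remapping During Spatial Reorientation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing CA1 place-cell activity recorded while
    disoriented animals reorient in two visually distinct rectangular
    chambers. Builds occupancy-normalised rate maps with speed filtering
    and Gaussian smoothing, quantifies geometric alignment with
    best-match-rotation and center-out angle statistics, classifies
    feature-sensitive versus feature-insensitive cells from
    geometry-aligned context similarity, decodes context and heading with
    population-vector and linear support-vector classifiers, measures
    across-context rate remapping, and scores digging behaviour with
    Bernoulli/Beta Bayes-factor models. A synthetic-session generator
    with known ground truth (cell classes, ensemble orientations, rate
    gains, dig outcomes) makes every stage testable without raw
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    jsonlite,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
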