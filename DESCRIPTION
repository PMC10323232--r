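Package: epievents
Title: Segmentation-Free Detection of Cell Extrusions and Other Cellular
    Events in Epithelial Movies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects cellular events (cell extrusions, divisions, sensory
    organ precursors) in time-lapse fluorescence movies of junction-labelled
    epithelia without segmenting or tracking cells. Overlapping
    spatiotemporal windows are classified by a convolutional-recurrent
    neural network (a per-frame convolutional encoder feeding a gated
    recurrent unit), the window probabilities are assembled into a
    whole-movie event probability map, and the map is post-processed
    (thresholding, minimum-volume filtering, watershed separation) into
    point detections. Includes training, reinforcement against recurring
    false positives, two-network ensembling, spatiotemporal detection
    metrics, ImageJ/Fiji ROI interchange, and a synthetic epithelium
    generator with planted, ground-truthed events.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    stats,
    tiff,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
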