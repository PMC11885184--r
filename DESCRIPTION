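Package: cytoblob
Title: Scale-Normalized Laplacian-of-Gaussian Blob Detection for Cytology Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multiscale blob detection for cervical-cytology micrographs and
    video frame sequences. Builds a Gaussian scale space, computes the
    scale-normalized Laplacian-of-Gaussian response volume, selects
    simultaneous space-scale extrema as cell-nucleus detections, converts each
    detection into a crop window via the radius law r = sqrt(2)*sigma, and
    extracts cell segments. Includes greedy one-to-one matching against
    ground-truth annotations with precision/recall/F-measure/accuracy
    reporting, a synthetic cytology-field generator with exact ground truth
    for end-to-end validation, a frame-sequence pipeline, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
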