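Package: silagekps
Title: Kernel Processing Score Estimation from Maize Silage Instance Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for assessing maize-silage kernel fragmentation from
    polygon- or box-based object recognition output. Sizes each kernel
    fragment by the minor axis of its minimum-area rotated bounding
    rectangle (rotating calipers), converts pixels to millimetres, and
    computes the Kernel Processing Score (KPS): the percentage of
    fragments with minor axis below the 4.75 mm sieve threshold.
    Includes COCO-style JSON annotation I/O, object-level detection
    evaluation (precision, recall, F1 and 11-point interpolated average
    precision at IoU 0.5), per-sequence KPS tables across processor-gap
    settings with Pearson/Shapiro-Wilk correlation analysis against
    annotation KPS, and a synthetic data generator with a simulated
    detector so the full pipeline is testable without field images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
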