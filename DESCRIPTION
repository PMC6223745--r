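Package: embryosync
Title: Morphometry and Synchronization Statistics for Somatic Embryo Maturation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies yield and developmental synchronization of conifer
    somatic embryo cultures from plate images and embryo-length tables.
    Provides image-based particle morphometry (binarization, 8-connectivity
    labeling, moment-equivalent-ellipse major-axis length in mm), the
    normalized length-distribution curve with full widths at 50/66/75% of
    maximum, coefficients of variation with McKay chi-square confidence
    intervals, area-based yield extrapolation per gram fresh weight,
    germination-rate summaries, and a seeded synthetic-data generator
    (length populations, rendered binary plate images with ground truth,
    aggregate-area distributions, germination counts) so the full pipeline
    is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
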