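Package: ecmquant
Title: Quantification of Melanoma Invasion and Extracellular Matrix Degradation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image- and score-level quantification pipelines for studies of
    melanoma invasion into collagenous dermal matrices. Implements spheroid
    invasion quantification (invasive area percentage and single-cell
    invasion counts) from nuclear-channel fluorescence stacks, structure
    tensor fibre-orientation analysis with an aligned-fraction statistic,
    DQ-collagen degradation scoring (per-cell degraded area and a weighted
    low/medium/high H-score), AFM surface roughness (Rq), and
    expression-signature scoring (qPCR relative expression, geometric-mean
    signature scores with median split, Kaplan-Meier/log-rank comparison).
    A synthetic-data generator produces images and expression datasets with
    machine-readable ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    survival,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
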