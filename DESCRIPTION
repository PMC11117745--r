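Package: semprep
Title: Semantic Preprocessing and Active Deep Learning for Fluorescence
    Section Labeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Semantic preprocessing (SP), bootstrapped semantic
    preprocessing (BSP) and its gradient-descent variant (GDBSP) for
    normalizing two-channel fluorescence microscopy sections toward a
    reference intensity distribution, fused with snapshot-ensemble active
    deep learning for automatic region-of-interest ground-truth
    generation.  Includes a compact encoder-decoder segmenter trained with
    Adadelta, patch-wise interpolation stitching of whole-section
    predictions, plurality-vote confidence maps, an accept/reject expert
    protocol with run accounting, and a seeded generator of synthetic
    two-channel sections with cohort-style acquisition inconsistency.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    stats,
    utils,
    tibble,
    png,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp
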