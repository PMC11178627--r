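Package: necaxr
Title: Enhancement, Augmentation and Evaluation Pipelines for Abdominal
    Radiograph Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for preparing low-contrast grayscale abdominal
    radiographs for three-class necrotising enterocolitis (NEC)
    classification. Implements a family of contrast and edge enhancement
    operators (Laplacian sharpening, global and contrast-limited adaptive
    histogram equalisation, percentile dynamic-range compression, unsharp
    masking, and illumination-map based low-light enhancement with a
    sparse edge-aware solver), a seedable stochastic augmentation suite
    (translation, cropping, rotation, flips, occlusion, noise, and
    intensity transforms), and two composed preprocessing pipelines that
    map a single-channel radiograph to a three-channel image for a
    convolutional backbone. A synthetic abdominal-radiograph phantom
    generator with ground-truth lesion masks and a stratified k-fold
    cross-validation harness allow every component to be exercised and
    benchmarked end-to-end without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    tools,
    Matrix,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse
LinkingTo:
    Rcpp
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
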