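Package: frplstm
Title: Histopathology Image Classification with Time-Frequency and
    Fuzzy-Recurrence Sequence Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies 2-D raster images (histopathological tissue and
    similar texture-rich material) by vectorizing each image into a time
    series, extracting sequential time-frequency features (instantaneous
    frequency and spectral entropy of a short-time power spectrum) and
    time-space features (fuzzy recurrence image entropy and fuzzy
    recurrence entropy of fuzzy recurrence plots built with fuzzy c-means
    clustering), and training a bidirectional long short-term memory
    network on the combined four-channel feature sequences under a
    class-modeling training-set construction. Includes evaluation metrics,
    repeated stratified k-fold cross-validation, and a synthetic texture
    generator for fully reproducible experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    jpeg,
    png,
    signal,
    stats,
    tiff,
    utils,
    withr
Suggests:
    e1071,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
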