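Package: spermdfi
Title: Single-Sperm Morphometry, DNA Fragmentation Index and Quality Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for single-cell sperm image analysis and DNA-integrity
    prediction. Segments sperm heads from brightfield images and measures
    head area, perimeter, length, width, circularity, midpiece width,
    acrosome area and acrosomal vacuole area; computes a per-cell DNA
    fragmentation index (DFI) from acridine-orange red/green fluorescence;
    fits centered-interaction linear models with forward selection, a
    single-hidden-layer neural network trained by Levenberg-Marquardt with
    validation early stopping, and logistic classifiers of Ln(DFI) rank
    categories; and evaluates predictions with percentile rank groups,
    Welch tests, enrichment percentiles, ROC/AUC and leave-one-donor-out
    reports. A synthetic-data module generates feature tables and paired
    brightfield/fluorescence rasters with known ground truth so the whole
    pipeline is testable without access to clinical images.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    EBImage,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
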