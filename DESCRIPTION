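Package: phenocast
Title: Plant-Level Phenotyping from Terrestrial LiDAR and Growth-Stage
    Forecasting with a Hybrid Stacked LSTM-GRU Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives per-plant height and crown area from terrestrial laser
    scanning point clouds of vegetable crop fields and forecasts both
    parameters at the next growth stage. The geometry pipeline removes
    outliers by k-nearest-neighbour distance thresholding, classifies ground
    points by progressive TIN densification, normalizes heights to the
    furrow-level ground surface, rasterizes a canopy height model, detects
    plant tops with a variable window filter and delineates crowns with
    marker-controlled watershed segmentation. The forecaster is a hybrid
    network of stacked LSTM and stacked GRU branches whose fully connected
    heads are concatenated into a final linear layer, trained by
    backpropagation through time with an adaptive-moment optimizer.
    Evaluation uses the symmetric mean absolute percentage error and
    per-pair logarithmic deviations. A synthetic-field simulator with known
    per-plant ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    FNN,
    graphics,
    grDevices,
    interp,
    jsonlite,
    Rcpp,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
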