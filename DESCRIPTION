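Package: spotdeconv
Title: Neural-Network Deconvolution of Spatial Transcriptomics Spots
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates cell-type composition of spatial transcriptomics spots
    from an annotated single-cell RNA-seq reference. Mixed transcriptional
    profiles with known cell-type proportions are simulated from the reference
    and used to train a fully connected neural network with a softmax head;
    the trained model deconvolutes each spot's measured (intrinsic) profile
    and, optionally, regularizes predictions spatially using simulated
    extrinsic profiles built from each spot's k nearest neighbours. Includes
    gradient-based interpretation of the network (gradient-times-input and
    integrated gradients), clustering of spots on predicted proportions, the
    evaluation-metric suite used in deconvolution benchmarking (Pearson and
    Lin's concordance correlation, RMSE, Jensen-Shannon divergence), and a
    synthetic-data generator producing references, spot lattices, and
    single-cell-resolution datasets with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pracma,
    FNN,
    mclust,
    rhdf5,
    optparse
Config/testthat/edition: 3
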