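Package: larvacount
Title: Automated Counting of Fluorescent Cells in Zebrafish Larvae from
    Multi-Well Plate Z-Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An automated pipeline for counting fluorescently labeled cells
    (e.g. EGFP-positive neutrophils) in zebrafish larvae imaged as per-well
    RGB Z-stacks across a 96-well plate. A convolutional (U-Net) segmenter
    locates the larva in each frame, the best-focus slice is selected by
    maximizing the variance of the Laplacian within the segmented region,
    fluorescence is isolated by to-zero intensity thresholding inside the
    high-resolution mask, and cells are counted by difference-of-Gaussian
    blob detection. Includes a ground-truthed synthetic plate simulator,
    HDF5 plate-scan storage, VGG Image Annotator polygon ingestion,
    segmentation training and evaluation utilities, and the population
    statistics (Mann-Whitney U, standard errors, linear regression) used to
    compare counting methods.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    rhdf5,
    jsonlite,
    png,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
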