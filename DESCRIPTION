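Package: fiberclot
Title: Clot Formation Analysis for Artificial-Lung Fiber Bundle Flow Chambers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying thrombus formation in hollow-fiber membrane
    oxygenator bundles using parametric rod-array flow chambers. Provides
    parametric chamber geometry (packing density, path length, fiber
    diameter) and the derived hemodynamic quantities (flow-rate/velocity
    conversion, hydraulic diameter, Reynolds number, cumulative fiber
    surface area, equivalent distances); a seeded synthetic-data generator
    producing voxel phantoms of clean and clotted chambers via stochastic
    surface accretion, plus pressure-drop/resistance time series; the
    micro-CT quantification pipeline (segmentation, clean-mask subtraction,
    edge cropping, longitudinal slice profiles, void-volume normalisation,
    replicate probability maps, axis projections, equivalent-distance slab
    volumes); resistance trajectory analysis against clot-free baselines;
    and donor-paired sign-flip permutation tests for group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
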