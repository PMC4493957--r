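Package: odemval
Title: Validation and Selection of ODE-Based Kinetic Models by Data Partitioning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A simulation framework for studying how the partitioning of
    multi-condition time-series data into training and validation sets affects
    the validation and selection of ordinary-differential-equation kinetic
    models. Ships a two-branch osmostress (HOG-like) benchmark model pair
    (a true structure and a simplified structure lacking one regulatory
    interaction), generates seeded noisy synthetic data over a cell-type by
    dose design, enumerates hold-out partitioning schemes and stratified
    random cross-validation folds, fits model structures by bounded nonlinear
    least squares, quantifies identifiability via the Fisher information
    matrix, and scores partitioning schemes by predictive power, wrong
    model-selection decisions, model separation and parameter-estimation
    quality.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Imports:
    deSolve,
    minpack.lm,
    pracma,
    MASS,
    jsonlite,
    yaml,
    parallel,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
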