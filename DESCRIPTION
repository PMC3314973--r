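Package: aslpattern
Title: Multi-Class Pattern Recognition for Arterial Spin Labeling Perfusion Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies cerebral blood flow from pulsed-continuous arterial spin
    labeling (pCASL) control/label image pairs, preprocesses per-scan flow maps
    into smoothed, averaged, within-subject mean-centered feature matrices, and
    discriminates pharmacological conditions with a sparse multinomial logistic
    regression trained by component-wise elastic-net updates under nested
    leave-one-subject-out cross-validation. Includes reference-class
    discrimination maps, non-zero coefficient overlap maps, voxelwise unpaired
    t-statistic maps, confusion-matrix significance statistics, scan-count
    learning curves, and a synthetic phantom generator with planted
    condition-specific effect clusters for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    dplyr,
    tidyr,
    tibble,
    ggplot2,
    rlang,
    generics,
    jsonlite,
    yaml,
    readr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
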