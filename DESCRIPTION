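Package: vibstab
Title: Elastic-Network Dynamics and Vibrational-Entropy Consensus Prediction
    of Mutation Effects on Protein Stability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained normal mode analysis of protein structures using
    elastic network models (a cutoff-based anisotropic network model and a
    sequence-dependent variant whose long-range spring constants are scaled by
    atom-type-weighted heavy-atom contacts). Derives per-residue fluctuations,
    deformation energies, cross-correlations, porcupine vectors and mode
    trajectories; computes vibrational entropy differences between wild-type
    and mutant structures; extracts graph-based structural signatures and
    residue-environment features (relative solvent accessibility, residue
    depth, secondary structure); and trains a Random-Forest consensus
    regressor of the change in folding free energy upon point mutation, with
    reverse-mutation augmentation, grouped 10-fold cross-validation and
    Pearson/RMSE evaluation including outlier-trimmed variants.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
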