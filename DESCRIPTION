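Package: trixs
Title: Time-Resolved X-Ray Solution Scattering Analysis of Triiodide Photodissociation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward modelling and structural refinement of time-resolved
    X-ray solution scattering (TR-XSS) difference signals from photoexcited
    triiodide in polar solvents. Provides Debye scattering with a
    Debye-Waller-like heterogeneity damping, anisotropic (P2) difference
    scattering from photoselection, solute-solvent cage terms built from a
    radial-distribution-function library with trilinear interpolation, a
    displaced-volume contribution and bulk solvent heating; a regularized
    per-timepoint chi-square refinement with multi-start optimization and
    sensitivity-based uncertainties; kinetics estimators for geminate-pair
    lifetimes, cage-escape probability, dissociation and angular speeds and
    kinetic-energy partitioning; and a synthetic-data generator emulating the
    ballistic dissociation / cage arrest / geminate recombination reaction
    scheme so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
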