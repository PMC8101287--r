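Package: bindkin
Title: Kinetic and Equilibrium Analysis of Receptor-Ligand Binding Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and nonlinear least-squares fitting of surface plasmon
    resonance (SPR) sensorgrams under 1:1 Langmuir and bivalent-analyte kinetic
    models, with local (single-concentration) and global (multi-concentration)
    fitting, goodness-of-fit statistics, and derived equilibrium dissociation
    constants. Companion tools cover steady-state affinity analysis of
    low-density sensorgram series, bead-proximity (AlphaScreen-style)
    cross-titration summaries with hook-effect detection, four-parameter
    logistic IC50 fitting of blockade titrations, and multimer-staining flow
    cytometry quantification (geometric MFI, FMO subtraction, percent-positive
    gating). Seeded synthetic-data generators emulate each assay design with
    known ground truth, enabling end-to-end parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    ggplot2,
    generics,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
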