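Package: cartkin
Title: Kinetic Modeling of CAR-T Cell Cytotoxicity from Impedance Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing chimeric antigen receptor T-cell
    (CAR-T) product function from real-time impedance (cell index)
    cytotoxicity assays. Implements a three-compartment ordinary
    differential equation model of tumor cells, CAR-T cells, and
    untransduced T cells with ratio-dependent Hill-type cytolysis and
    cytolysis-driven effector proliferation; per-product normalization and
    linear cell-count/cell-index calibration; staged multi-start bounded
    least-squares parameter estimation; error and global sensitivity
    analysis with correlation-based identifiability diagnostics;
    nonparametric cohort comparison of estimated parameters against
    clinical outcome labels; and a synthetic cohort generator emulating
    the assay protocol for end-to-end validation.
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
    jsonlite,
    rlang,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
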