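Package: adheretraj
Title: Latent-Class Trajectories of Medication Adherence from Tacrolimus
    Trough Levels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for trajectory analysis of immunosuppressant medication
    adherence in organ-transplant cohorts. Computes the medication level
    variability index (MLVI, the rolling-window standard deviation of
    tacrolimus trough levels) from raw assay records, fits finite mixtures
    of linear latent growth curves by maximum likelihood with missing
    occasions (growth mixture models), enumerates the number of latent
    trajectory classes with information criteria, entropy, and
    likelihood-ratio tests (including a parametric bootstrap), and profiles
    the resulting classes: posterior classification quality, separation of
    patient-mean MLVI with threshold analysis, and between-class
    comparisons of outcomes and demographics by exact and rank-based
    tests. Includes a synthetic cohort generator that doubles as an oracle
    for the MLVI computation, so the whole pipeline is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lubridate,
    MASS,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
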