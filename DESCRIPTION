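Package: mabscale
Title: Cross-Species Clearance and Bioavailability Translation for
    Therapeutic Antibodies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for translating monoclonal antibody pharmacokinetics
    across rat, cynomolgus monkey and human. Ships a curated 25-antibody
    cross-species table of weight-normalized clearance and subcutaneous
    bioavailability, non-compartmental analysis of single-dose
    concentration-time profiles (terminal slope selection,
    linear-up/log-down AUC, extrapolation gating, anti-drug-antibody
    screening), a nonlinear mixed-effects allometric clearance model
    (Laplace marginal likelihood with adaptive Gauss-Hermite validation and
    cluster bootstrap), single-species scaling of human clearance with
    fold-error summaries, and Spearman/least-squares cross-species
    correlation analyses. A two-compartment simulator with first-order
    subcutaneous absorption, assay noise, quantification limits and
    immunogenicity effects provides ground-truth data for validation.
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
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LazyData: false
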