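Package: fishhic
Title: Reconciling FISH Distance Distributions with Hi-C Contact Probabilities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating population-averaged Hi-C contact probabilities to
    single-cell FISH spatial distance measurements under a Generalized Rouse Model
    for Chromosomes (GRMC). Provides the exact closed-form map between mean pair
    distance and contact probability for a harmonic chain with CTCF/cohesin loop
    cross-links and its numerical inverse; Redner-des Cloizeaux distance
    distributions for chromatin; two-subpopulation mixture fitting of FISH
    cumulative distance distributions with Kolmogorov-Smirnov diagnostics;
    continuous subpopulation deconvolution by nonnegative Tikhonov-regularised
    least squares; a loop-anchored Rouse-chain Langevin simulator with exact
    normal-mode pair statistics; and synthetic-data generators plus readers for
    FISH distance tables, Hi-C contact counts and BEDPE loop anchors, so the
    FISH-Hi-C paradox can be demonstrated, diagnosed and resolved end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
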