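Package: warmclip
Title: Factorial Warming x Clipping Grassland Analysis Pipeline
Version: 0.1.0
Authors@R:
    person("warmclip", "developers", email = "warmclip@example.org",
           role = c("aut", "cre"))
Description: Reusable implementation of the computational analyses used in
    paired-factorial grassland warming x clipping experiments: factorial
    effect estimation (warming, clipping, observed and predicted-additive
    combined effects) with paired and sign-flip permutation paired t tests
    and additive/synergistic/antagonistic interaction classification;
    functional gene microarray (GeoChip-style) probe-level preprocessing
    (SNR/flag quality control, three-level normalization, detection filters,
    relative-abundance rescaling and log transform) and category-level
    treatment effects; Bayesian Metropolis-Hastings inversion of a six-pool
    terrestrial carbon (TECO-style) model for the Q10 of heterotrophic soil
    respiration; a two-source carbon-isotope mixing model; and
    dissimilarity-based community statistics (Morisita-Horn dissimilarity,
    pairwise permutational MANOVA, Mantel tests, alpha diversity). A
    synthetic-data module generates every input with known ground truth so
    the whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
Config/testthat/edition: 3
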