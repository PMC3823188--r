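Package: crossfeedr
Title: Individual-Based Simulation of Spatial Cross-Feeding Microbial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An agent-based 'diffusion model' of three-strain microbial
    communities growing on an agarose surface, in which a cooperator strain
    releases adenine and requires lysine, a partner strain releases lysine on
    death and requires adenine, and a cheater strain consumes lysine without
    releasing adenine. Cells occupy a 3-D lattice, accumulate metabolites by
    Michaelis-Menten uptake from reaction-diffusion concentration fields
    solved on a dual-resolution grid, divide when quotas are met (with
    experimentally motivated cell-rearrangement rules), and die
    stochastically. The package provides growth protocols (random lawns,
    periodic symmetric lattices, stripes, high-density spots, periodic
    mixing, well-mixed liquid), spatial statistics (the partner association
    index in 2-D and 3-D neighborhoods), a fluorescence-image pixel
    classifier with a synthetic image generator, renders, and tidy
    trajectory outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    generics,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    png,
    optparse,
    withr
Config/testthat/edition: 3
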