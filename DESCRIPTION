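Package: kinprims
Title: Kinematic Primitives from Curvature and Torsion Surfaces of
    Flexible Appendage Movements
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Decomposes movements of a flexible three-dimensional
    appendage (such as an octopus arm backbone tracked as a sequence of
    midline curves) into elementary kinematic units.  A movement is
    represented as a pair of curvature and torsion surfaces over arm
    index and normalized time, each surface is approximated by a weighted
    sum of bivariate Gaussians selected by the Bayesian Information
    Criterion, Gaussians are clustered into a vocabulary of kinematic
    units with a weighted per-parameter distance and the gap statistic,
    movements are encoded as weight vectors over the shared vocabulary
    and classified into prototypes, and new movements are synthesized
    from unit combinations by integrating the Frenet-Serret equations.
    Includes a synthetic-movement generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp
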