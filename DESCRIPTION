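Package: myxofruit
Title: Simulation and Volumetric Analysis of Spore Clustering in Myxococcus
    xanthus Fruiting Bodies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how jamming and contact-dependent C-signaling
    organize spores into dense pockets inside Myxococcus xanthus fruiting
    bodies. Provides a one-dimensional circular-track simulator of cell
    movement, spore jamming and threshold sporulation; a two-dimensional
    stochastic agent-based model of flexible self-propelled rods with
    A/S-motility, slime-trail following, periodic reversals, Metropolis
    collision resolution and alignment-gated end-to-end C-signaling;
    moment-based ellipse fitting and radial/angular intensity profiling of
    three-dimensional grayscale volumes such as optical coherence tomography
    scans of mounds; kernel-smoothed spore point-pattern statistics; and
    synthetic-data generators (cone-shaped mound volumes with planted
    high-density pockets, uniform-ellipse phantoms, clustered spore patterns)
    that return ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    tiff,
    png,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
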