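Package: plumadrum
Title: Colour-Pattern Geometry and Phylogenetic Regression for Plumage and
    Drumming Signals
Version: 0.1.0
Authors@R:
    person("Plumadrum", "Developers", email = "plumadrum@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying head-plumage colour patterns from masked
    PNG images (CIE Lab segmentation into discrete colour patches, chromatic
    and achromatic boundary strength, scaled Simpson colour diversity, red
    patch proportion) and for relating those metrics to acoustic display
    traits across species with phylogenetic generalized least squares using
    maximum-likelihood estimation of Pagel's lambda. Includes generators for
    synthetic plumage images with analytic ground truth and for trait tables
    evolved on simulated phylogenies, a neighbour-joining colour tree from
    pairwise image distances, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
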