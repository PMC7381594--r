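Package: frillmorph
Title: Geometric Morphometrics and Phylogenetic Heterochrony Analysis of
    Skull Landmark Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for landmark-based geometric morphometrics on fossil
    skull data: TPS file input/output with semilandmark resampling and
    bilateral mirroring, generalized Procrustes superimposition,
    phylogenetic principal components analysis, the covariance-ratio test
    of landmark modularity with a random-partition null, fossil
    time-scaling of phylogenies from stratigraphic appearance dates,
    independent-contrasts and squared-change-parsimony comparative
    methods, maximum-likelihood Brownian-motion model fitting with
    lambda/kappa/delta tree transformations, and an ontogenetic-vector
    procedure for inferring heterochrony (peramorphosis and
    paedomorphosis) from allometric regression scores. Includes a
    synthetic landmark-data generator with known phylogenetic, modular,
    and allometric structure so every pipeline stage can be verified
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    jsonlite
Suggests:
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
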