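Package: RoseoFBA
Title: Constraint-Based Analysis of Roseobacter-Clade Metabolism with
    Light and Motility Energetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Flux balance and flux variability analysis for genome-scale
    metabolic models of marine aerobic anoxygenic phototrophs such as
    Dinoroseobacter shibae. Implements SBML input/output, gene-protein-
    reaction logic, dual biomass reactions built from macromolecule mass
    fractions, carbon-atom-normalized uptake bounds, a flagellar-motor
    proton drain, a two-reaction photosystem, condition-grid campaign
    simulation with flux-distribution grouping, and downstream analyses
    of DMSP degradation routes, elevated DMS production, aerobic
    denitrification, metabolic branch points and single-gene knockout
    phenotypes. A seeded generator produces a reduced core network with
    ground-truth annotations so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    xml2,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    boot
Config/testthat/edition: 3
RoxygenNote: 7.3.3
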