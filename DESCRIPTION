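Package: shootsim
Title: Branching-Phenotype Simulation for Prostrate Clonal Herbs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates whole-shoot branching phenotypes of prostrate clonal
    herbs from a bud-activation model in which a net root stimulus (NRS)
    decays geometrically with nodal distance from the basal root system and
    each axillary bud's response is moderated by an outgrowth potential (OP)
    inherited from its parent apical bud. Provides calibration of the
    geometric common ratio from primary-stem node counts, recursive
    enumeration and classification of every bud position (unemerged, short
    shoot, unbranched branch, branched branch), phenotype count tables by
    primary-stem node position and branching order, Newick export of the
    branching topology, species presets for Trifolium repens and
    Tradescantia fluminensis, and a discrete two-sample Kolmogorov-Smirnov
    test (exact enumeration or permutation) for comparing predicted and
    observed branching distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ape,
    optparse,
    withr
Config/testthat/edition: 3
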