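Package: hingeShear
Title: Quantitative Assignment of Hinge and Shear Mechanisms to Protein
    Domain Movements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Classifies protein domain movements as hinge (interface-creating)
    or shear (interface-preserving) from changes in interdomain residue
    contacts between two conformations. Detects heavy-atom residue contacts
    at a 4 Angstrom cutoff with bending-region and near-axis exclusions,
    builds the directed bipartite dynamic contact graph, decomposes it into
    the four elemental contact-change types (maintained, exchanged-partner,
    exchanged-pair, new), and applies a logistic model to the resulting
    count vector. Also provides screw-axis analyses (mechanical hinges,
    effective hinge axis, pitch, closure versus twist), two-proportion
    significance tests, training and cross-validation of the logistic
    classifier, and deterministic synthetic fixture generators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
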