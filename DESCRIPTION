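Package: tmbundle
Title: Consensus Modelling of Transmembrane Helix Bundles from Predicted Contacts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building and judging alpha-carbon models of
    transmembrane alpha-helical bundles from coevolution-predicted
    residue contacts.  Reads ranked contact lists in several dialects
    (CASP-RR, PSICOV, GREMLIN, EVfold), normalizes and combines them on
    a common rank-transformed scale, parses contact maps into
    parallel/antiparallel helix-packing blocks with dynamic-programming
    boundary refinement, scores candidate Ca traces with a soft
    Gaussian pseudo-centroid contact function, measures bundle
    compactness as an axial radius of gyration about a cap-derived
    bundle axis, compares model ensembles by environment-weighted RMSD
    and projects them into a low-dimensional fold space, and selects
    consensus model pools by top-slice culling of score-versus-
    compactness plots.  A synthetic generator of ideal helix bundles,
    oracle contacts, topology tracks and decoy structures supports
    fully self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    igraph
Suggests:
    testthat (>= 3.0.0),
    cluster,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
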