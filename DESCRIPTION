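Package: pathcolor
Title: Pathway Involvement Prediction for Small Molecules from
    Atom-Coloring Substructure Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds machine-learning-ready datasets linking small-molecule
    structures to biochemical pathway membership and evaluates binary
    classifiers on them.  Compounds are featurized from MDL V2000 molfiles
    by iterative neighborhood atom coloring, giving substructure occurrence
    counts; pathway feature vectors are obtained by aggregating the counts
    of member compounds.  Compound and pathway entries are cross-joined
    into labeled pairs, a multi-layer perceptron is trained under repeated
    stratified shuffle-split cross-validation, and performance is summarized
    with Matthews correlation coefficients at the iteration, compound,
    pathway, and hierarchy-level scopes, including overall (summed-count)
    MCC and effect-size comparisons.  A synthetic-data generator plants
    substructure motifs into random molecular graphs so the full pipeline
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    nnet,
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
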