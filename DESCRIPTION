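Package: combotan
Title: Gaussian Shape and Pharmacophore Color Tanimoto Similarity for
    Bioassay Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes ROCS-style three-dimensional molecular similarity
    scores: the shape-Tanimoto (ST) from analytic Gaussian overlap volumes,
    the color-Tanimoto (CT) from typed pharmacophore feature ("color atom")
    overlaps, and their sum, the combo-Tanimoto (ComboT).  Rigid-body
    superposition of conformer pairs is optimized either for shape overlap
    (ST-optimized) or for feature overlap (CT-optimized), yielding six
    similarity measures per pair.  On top of the scoring layer the package
    implements a per-bioassay statistical framework that partitions tested
    compounds into noninactive-noninactive (NN) and noninactive-inactive
    (NI) pairs, summarizes per-assay score differences, aggregates across
    assay categories, and flags outlier assays whose actives separate
    clearly from inactives in shape and feature space.  A synthetic
    conformer and assay generator makes the whole pipeline testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineR,
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
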