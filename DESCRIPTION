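Package: assocnet
Title: Ensemble Association Network Inference for Microbial Community Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers signed association networks from abundance, count or
    presence/absence tables such as OTU tables from 16S rDNA surveys.
    Combines multiple association measures (correlations, dissimilarities,
    mutual information, incidence-based tests), selects candidate edges by
    manual or automatic thresholds, assesses edge significance with
    compositionality-aware renormalized permutation nulls together with
    bootstrap confidence distributions, merges dependent measure-specific
    p-values with Brown's method, applies multiple-testing correction, and
    exports annotated networks (GML, GraphViz dot, edge tables). Includes a
    synthetic-community generator with planted associations for validation,
    taxonomic lineage handling with parent-child edge exclusion, sample
    metadata nodes, and a reproducible two-launch resampling protocol with
    persisted permutation and bootstrap distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    biomformat
Suggests:
    vegan,
    pROC,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
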