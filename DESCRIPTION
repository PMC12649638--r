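Package: polypnet
Title: Physiology, Energetics and Co-Expression Network Analysis of
    Reattached Coral Polyps
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis pipeline for feeding experiments on reattached coral
    polyps (Pocillopora damicornis): calculators for symbiont density,
    chlorophyll a+c2 content, caspase-3 activation and cellular energy
    allocation (Ea, Ec, CEA); normality-routed two-group statistics with
    Benjamini-Hochberg adjustment and PCA; CPM-based differential-expression
    screening; and a correlation-based co-expression module detection
    procedure (Ward.D2 clustering of the 1-|r| distance, minimum-size tree
    cut, module eigengenes, eigengene merging, kME and module-trait
    inference) with hypergeometric term enrichment. A synthetic-data
    generator with planted modules and trait effects makes every stage
    testable without the original specimens.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    car,
    mclust,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
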