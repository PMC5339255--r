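Package: vorisk
Title: Voronoi Tessellation Network Analysis for Disease Risk Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds score-based gene-variant maps from gene disease-association
    Z-scores and per-locus variant deleteriousness scores (1-SIFT or PolyPhen),
    computes Voronoi tessellations with normalized cell densities, derives a
    density threshold for clustering by fitting a chi-square-family model to the
    background density distribution, detects clusters of high-density cells over
    the Gabriel (qualified Delaunay) neighbor graph, and computes per-gene risk
    scores, relative risk between gene carriers, and relative disease
    association between gene sets. Includes a seeded synthetic-data generator
    for end-to-end validation with planted cluster structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deldir,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
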