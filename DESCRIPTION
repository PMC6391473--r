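Package: nfkbscreen
Title: Network-Centric Screening for Inhibitors of TNF-Induced NF-kB Signaling
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for network-centric discovery of small-molecule
    inhibitors of TNF-induced NF-kB signaling. Computes connectivity features
    between compound and gene-knockdown differential-expression signatures over
    a protein-interaction network (direct Pearson correlation, indirect
    partner-fraction correlation, and signature-strength features), trains a
    random-forest classifier for compound-target prediction with hypergeometric
    pathway enrichment and mean-pathway-correlation candidate ranking, extracts
    descriptors (AUC, Max, t_max, Rate_in, Rate_out) from single-cell nuclear
    NF-kB translocation time courses with permutation-based condition
    comparison, and estimates melting temperatures and thermal shifts from
    dye-based melt curves. Includes seeded synthetic-data generators with
    planted ground truth so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    minpack.lm,
    pracma,
    randomForest,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
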