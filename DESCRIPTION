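Package: wborda
Title: Multivariate Time Series Similarity Search by Weighted BORDA Voting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Dimension-combination k-nearest-neighbour similarity search for
    multivariate time series (MTS) such as multichannel physiological
    recordings. Each MTS item is reduced to principal-component series by
    covariance PCA; a constrained dynamic time warping (DTW) search is run
    per component series; per-dimension hits are truncated into candidate
    multivariate sequences; and candidates are ranked either by classical
    BORDA counts (S_BORDA) or by a weighted BORDA score (S_WBORDA) that
    incorporates the actual distance gaps and eigenvalue-derived dimension
    weights. Includes 1-NN classification with repeated stratified k-fold
    cross-validation, a component-count scan, the Wilcoxon signed-rank
    comparison of measures, and seeded synthetic generators for labelled
    MTS collections and long series with planted motifs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    jsonlite
Config/testthat/edition: 3
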