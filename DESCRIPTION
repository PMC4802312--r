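Package: unibic
Title: Trend-Preserving Biclustering of Gene Expression Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers trend-preserving biclusters (submatrices whose rows are
    pairwise order-preserving or order-reversing) in real-valued gene
    expression matrices.  Candidate biclusters are seeded by longest common
    subsequences between rows of a rank index matrix, grown into strict
    order-preserving blocks, and extended into error-tolerant trend-preserving
    biclusters that may include sign-reversed genes.  Includes quantile-based
    separation and rank granulation preprocessing, a synthetic benchmark
    generator implanting six classes of biclusters (trend-preserving,
    column-constant, row-constant, shift-scale, shift, scale) into Gaussian
    backgrounds with controlled overlap, and Jaccard-based relevance and
    recovery scoring against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
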