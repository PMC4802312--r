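#' Jaccard similarity of two gene sets
#'
#' `|b1 n b2| / |b1 u b2|`, the gene-set similarity used to compare a
#' discovered bicluster against a genuine one.
#'
#' @param b1,b2 vectors of gene identifiers or row indices (treated as sets).
#' @return A value in `[0, 1]`.
#' @export
jaccard <- function(b1, b2) {
  b1 <- unique(b1); b2 <- unique(b2)
  u <- length(union(b1, b2))
  if (u == 0L) stop_validation("both sets are empty")
  length(intersect(b1, b2)) / u
}

#' Match score between two sets of biclusters
#'
#' `S(M1, M2) = (1/|M1|) * sum over b1 in M1 of max over b2 in M2 of
#' jaccard(b1, b2)`: the average similarity of the biclusters in `M1` with
#' their best counterparts in `M2`.  An empty `M2` scores 0.
#'
#' @param M1,M2 lists of gene sets (vectors).
#' @return A value in `[0, 1]`.
#' @export
match_score <- function(M1, M2) {
  if (length(M1) == 0L) stop_validation("M1 must be nonempty")
  if (length(M2) == 0L) return(0)
  mean(vapply(M1, function(b1) {
    max(vapply(M2, function(b2) jaccard(b1, b2), 0))
  }, 0))
}

# coerce ground truth / unibic results / plain lists to lists of gene sets,
# or of (gene, condition) cell sets when cells = TRUE
gene_sets <- function(x, cells = FALSE) {
  as_set <- function(rows, cols) {
    if (!cells) return(rows)
    as.vector(outer(rows, cols, paste, sep = ":"))
  }
  if (inherits(x, "unibic_ground_truth"))
    return(lapply(x$biclusters, function(b) as_set(b$rows, b$cols)))
  if (inherits(x, "unibic_result") ||
      (is.list(x) && length(x) && inherits(x[[1L]], "unibic_bicluster")))
    return(lapply(x, function(b) as_set(b$rows, b$cols)))
  if (is.list(x)) {
    if (cells) stop_param("cell-level scoring needs bicluster objects with columns")
    return(x)
  }
  stop_param("cannot interpret object as a set of biclusters")
}

#' Relevance and recovery of discovered biclusters
#'
#' Recovery is the match score `S(G, D)` of the genuine biclusters against
#' the discovered ones (how well each implanted bicluster was found);
#' relevance is `S(D, G)` (how well each discovered bicluster corresponds to
#' a genuine one).  Scoring is on gene (row) sets; orientation flags are
#' ignored.  An empty discovery scores 0 on both rather than erroring, so
#' failed runs remain comparable.
#'
#' @param truth a `unibic_ground_truth` or list of gene sets.
#' @param found a `unibic_result`, list of [bicluster()]s, or list of gene
#'   sets.
#' @param cells score on (gene, condition) cell sets instead of gene sets;
#'   off by default (gene sets are the standard comparison), provided for
#'   cross-tool comparisons that weigh column agreement too.
#' @return Named numeric vector `c(relevance = , recovery = )`.
#' @export
relevance_recovery <- function(truth, found, cells = FALSE) {
  G <- gene_sets(truth, cells = cells)
  D <- gene_sets(found, cells = cells)
  if (length(D) == 0L) return(c(relevance = 0, recovery = 0))
  c(relevance = match_score(D, G), recovery = match_score(G, D))
}
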