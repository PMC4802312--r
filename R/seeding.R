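# log of the expected number of a-row, b-column order-preserving submatrices
# in a random n x m matrix (union bound over row sets and ordered column
# selections, rows treated as independent uniform permutations):
#   U(a, b) = [m!/(m-b)!] * C(n, a) * (1/b!)^a
log_submatrix_bound <- function(a, b, n, m) {
  lgamma(m + 1) - lgamma(m - b + 1) + lchoose(n, a) - a * lgamma(b + 1)
}

#' Partition parameter for seed search
#'
#' Computes the largest `k` such that any significant order-preserving
#' bicluster must span more than `k` rows, from the expected-count bound
#' `U(a, b) = [m!/(m-b)!] * C(n, a) * (1/b!)^a`: over column counts `b` from
#' the minimum significant subsequence length up to `m`, the smallest row
#' count `a` with `U(a, b) <= alpha` is found, and `k` is the minimum of those
#' row counts minus one, clamped to `[1, n-1]`.  Splitting the rows into `k`
#' groups then guarantees (pigeonhole) that every significant bicluster
#' contributes at least one within-group row pair.
#'
#' @param n,m matrix dimensions.
#' @param alpha significance level.
#' @return Integer `k` in `[1, n-1]`.
#' @export
compute_k <- function(n, m, alpha = 0.05) {
  if (n < 2 || m < 2) stop_param("need n >= 2 and m >= 2")
  b_min <- min_significant_length(m, alpha)
  a_grid <- 2:n
  best_a <- Inf
  for (b in seq(from = min(b_min, m), to = m)) {
    lu <- log_submatrix_bound(a_grid, b, n, m)
    hit <- which(lu <= log(alpha))
    if (length(hit)) best_a <- min(best_a, a_grid[hit[1L]])
    if (best_a == 2) break
  }
  k <- if (is.finite(best_a)) best_a - 1L else n - 1L
  as.integer(min(max(k, 1L), n - 1L))
}

#' Split rows into balanced groups
#'
#' A seeded uniform shuffle of the row indices followed by contiguous
#' splitting into `k` groups of size `floor(n/k)` or `ceiling(n/k)`.
#'
#' @param n row count.
#' @param k number of groups, `1 <= k <= n`.
#' @param rng_seed integer seed making the shuffle reproducible.
#' @return A list of `k` integer vectors partitioning `1..n`.
#' @export
partition_rows <- function(n, k, rng_seed = 1L) {
  if (k < 1 || k > n) stop_param("k must be in [1, n], got k = ", k)
  k <- as.integer(k); n <- as.integer(n)
  perm <- withr::with_seed(rng_seed, sample.int(n))
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  lapply(seq_len(k), function(g) sort(perm[starts[g]:ends[g]]))
}

#' Enumerate significant LCS seeds within row groups
#'
#' For every unordered pair of rows inside each group, the LCS of their
#' index-matrix orderings is computed; pairs reaching `threshold` are kept,
#' each with one deterministically chosen subsequence, and listed longest
#' first (ties: smaller `(row_a, row_b)` lexicographically).
#'
#' @param Y index matrix from [index_matrix()].
#' @param groups list of row-index groups from [partition_rows()].
#' @param threshold minimum significant length (at least 3).
#' @return A list of class `unibic_seeds`: `seeds` (a list, each with `row_a`,
#'   `row_b`, `sequence`, `length`), `k`, and `threshold`.
#' @export
generate_seeds <- function(Y, groups, threshold) {
  if (threshold < 3) stop_param("threshold must be >= 3")
  raw <- .generate_seeds_cpp(Y, groups, as.integer(threshold))
  ord <- order(-raw$length, raw$row_a, raw$row_b)
  seeds <- lapply(ord, function(s) {
    list(row_a = raw$row_a[s], row_b = raw$row_b[s],
         sequence = raw$sequence[[s]], length = raw$length[s])
  })
  structure(list(seeds = seeds, k = length(groups),
                 threshold = as.integer(threshold)),
            class = "unibic_seeds")
}

#' @export
print.unibic_seeds <- function(x, ...) {
  cat(sprintf("%d seed(s) from %d group(s), threshold %d\n",
              length(x$seeds), x$k, x$threshold))
  invisible(x)
}
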