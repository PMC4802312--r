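# Independent oracles and fixture builders shared across the suite.  These
# deliberately avoid the package's own C++ routines: brute force and plain-R
# patience sorting stand on their own so the dynamic program is checked
# against something it does not share code with.

# maximum common-subsequence length by enumerating all subsequences of `a`
# and testing each for order-preserved membership in `b`
bf_lcs_length <- function(a, b, subsets = NULL) {
  n <- length(a)
  if (is.null(subsets)) subsets <- all_subsets(n)
  best <- 0L
  for (idx in subsets) {
    if (length(idx) <= best) next
    pos <- match(a[idx], b)
    if (anyNA(pos)) next
    if (!is.unsorted(pos, strictly = TRUE)) best <- length(idx)
  }
  best
}

all_subsets <- function(n) {
  lapply(seq_len(2^n) - 1L, function(mask) which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0))
}

# longest strictly increasing subsequence, O(n^2) plain R (patience sorting)
lis_length_r <- function(x) {
  tails <- numeric(0)
  for (v in x) {
    j <- which(tails >= v)
    if (length(j)) tails[j[1L]] <- v else tails <- c(tails, v)
  }
  length(tails)
}

# is a bicluster exactly trend-preserving in the raw matrix: every member
# row's values along the consensus, negated for reversed members, must be
# non-decreasing
bic_exactly_trend_preserving <- function(bic, x) {
  all(vapply(seq_along(bic$rows), function(i) {
    v <- x[bic$rows[i], bic$cols]
    if (bic$orientation[i] == "-") v <- -v
    !is.unsorted(v)
  }, TRUE))
}

# every pair of rows of x[rows, cols] order-preserving or order-reversing
submatrix_trend_preserving <- function(x, rows, cols) {
  sub <- x[rows, cols, drop = FALSE]
  for (i in seq_along(rows)) {
    ord <- order(sub[i, ])
    for (j in seq_along(rows)) {
      if (j <= i) next
      v <- sub[j, ord]
      if (is.unsorted(v) && is.unsorted(rev(v))) return(FALSE)
    }
  }
  TRUE
}

# exhaustive maximum area over strict order-preserving submatrices with at
# least `min_rows` rows and at least 3 columns
op_max_area <- function(x, min_rows = 3L) {
  m <- ncol(x)
  best <- 0L
  for (sz in 3:m) {
    for (S in utils::combn(m, sz, simplify = FALSE)) {
      keys <- apply(x[, S, drop = FALSE], 1L,
                    function(v) paste(rank(v), collapse = ","))
      tab <- table(keys)
      if (max(tab) >= min_rows) best <- max(best, max(tab) * sz)
    }
  }
  best
}

# a random expression matrix with a strict order-preserving block implanted
# at the given rows/cols (all rows of the block share one rank pattern)
implant_strict_op <- function(x, rows, cols, rng_seed = 1L) {
  withr::with_seed(rng_seed, {
    pattern <- sample(seq_along(cols))
    for (r in rows) x[r, cols[pattern]] <- sort(stats::runif(length(cols)))
  })
  x
}

random_perm <- function(m) sample.int(m)

# all m! permutations of 1..m as a list of integer vectors
all_permutations <- function(m) {
  if (m == 1L) return(list(1L))
  out <- list()
  for (p in all_permutations(m - 1L)) {
    for (pos in 0:(m - 1L)) {
      out[[length(out) + 1L]] <- append(p, as.integer(m), after = pos)
    }
  }
  out
}
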