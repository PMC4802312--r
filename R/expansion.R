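#' Grow a seed into a strict order-preserving block
#'
#' Starting from the seed's two rows and common subsequence, repeatedly adds
#' the candidate row whose index-matrix ordering retains the longest common
#' subsequence with the current consensus (ties: smaller row index), shrinking
#' the consensus to that subsequence.  Growth stops when committing the best
#' candidate would leave the block with more rows than consensus columns, or
#' when no candidate retains at least 3 columns; the block from the stage
#' before the stopping condition is returned.
#'
#' @param seed a list with `row_a`, `row_b` and `sequence` (one element of
#'   [generate_seeds()]`$seeds`).
#' @param Y index matrix.
#' @return A list of class `unibic_block` with sorted `rows` and the ordered
#'   consensus `cols`.
#' @export
grow_strict <- function(seed, Y) {
  res <- .grow_strict_cpp(Y, seed$row_a, seed$row_b,
                          as.integer(seed$sequence))
  structure(list(rows = res$rows, cols = res$cols), class = "unibic_block")
}

#' Extend a strict block with error-tolerant columns
#'
#' For each column outside the consensus, the insertion position minimizing
#' the fraction of block rows whose value there breaks the non-decreasing
#' order against the flanking consensus columns is found.  The candidate with
#' the smallest violation fraction (ties: smaller column index) is inserted at
#' its best position (ties: leftmost) as long as the fraction does not exceed
#' `col_error`; the process repeats until no column qualifies.  Rows are
#' unchanged.
#'
#' @param block a `unibic_block` from [grow_strict()].
#' @param disc the granulated integer matrix the block lives in.
#' @param col_error tolerated fraction of violating rows in `[0, 1)`.
#' @return A [bicluster()] with the extended consensus, all members original
#'   orientation, `core_rows` equal to the block rows, and no p-value yet.
#' @export
extend_columns <- function(block, disc, col_error = 0.3) {
  if (col_error < 0 || col_error >= 1)
    stop_param("col_error must be in [0, 1)")
  rows <- block$rows
  cons <- block$cols
  m <- ncol(disc)
  vals <- disc[rows, , drop = FALSE]
  repeat {
    cand <- setdiff(seq_len(m), cons)
    if (length(cand) == 0L) break
    L <- length(cons)
    cv <- vals[, cons, drop = FALSE]
    # viol[p, c]: fraction of rows for which candidate c cannot sit at
    # insertion position p (0-based: p = 0 is before the first column)
    best_frac <- rep(Inf, length(cand))
    best_pos <- rep(NA_integer_, length(cand))
    for (p in 0:L) {
      ok <- matrix(TRUE, length(rows), length(cand))
      if (p > 0L) ok <- ok & (cv[, p] <= vals[, cand, drop = FALSE])
      if (p < L) ok <- ok & (vals[, cand, drop = FALSE] <= cv[, p + 1L])
      frac <- colMeans(!ok)
      better <- frac < best_frac
      best_frac[better] <- frac[better]
      best_pos[better] <- p
    }
    pick <- which(best_frac <= col_error)
    if (length(pick) == 0L) break
    pick <- pick[order(best_frac[pick], cand[pick])][1L]
    cons <- append(cons, cand[pick], after = best_pos[pick])
  }
  bicluster(rows = rows, cols = cons, core_rows = block$rows)
}

#' Extend a bicluster with error-tolerant rows, original or reversed
#'
#' For every row outside the bicluster (and outside `used`), the LCS length of
#' the consensus against the row's ordering (`L+`) and against its reverse
#' (`L-`) is computed.  The better orientation is accepted when its error
#' `1 - max(L+, L-)/|consensus|` is at most `row_error`.  Accepted rows join
#' in decreasing `max(L+, L-)` order (ties: smaller row index), reversed
#' orientation recorded where `L- > L+`.  The consensus columns never change
#' in this phase.
#'
#' @param bic a [bicluster()] (typically from [extend_columns()]).
#' @param Y index matrix.
#' @param row_error tolerated error in `[0, 1)`.
#' @param used optional row indices excluded from consideration.
#' @return The enlarged [bicluster()].
#' @export
extend_rows <- function(bic, Y, row_error = 0.15, used = integer(0)) {
  if (row_error < 0 || row_error >= 1)
    stop_param("row_error must be in [0, 1)")
  cons <- bic$cols
  scan <- .consensus_lcs_scan_cpp(Y, as.integer(cons))
  best <- pmax(scan[, 1L], scan[, 2L])
  err <- 1 - best / length(cons)
  cand <- setdiff(which(err <= row_error), c(bic$rows, used))
  if (length(cand) == 0L) return(bic)
  cand <- cand[order(-best[cand], cand)]
  orient <- ifelse(scan[cand, 2L] > scan[cand, 1L], "-", "+")
  bicluster(rows = c(bic$rows, cand),
            orientation = c(bic$orientation, orient),
            cols = cons, p_value = bic$p_value, core_rows = bic$core_rows)
}

#' Significance value of a bicluster
#'
#' The expected number of order-preserving submatrices with `a = |core rows|`
#' rows and `b = |consensus columns|` columns in a random `n x m` matrix,
#' `U(a, b) = [m!/(m-b)!] C(n, a) (1/b!)^a`, capped at 1.  This is a
#' conservative bound on the probability that a block of the observed size
#' arises by chance, monotone decreasing in both `a` and `b` over the useful
#' range.
#'
#' @param bic a [bicluster()].
#' @param n,m dimensions of the matrix searched.
#' @return A value in `[0, 1]`.
#' @export
bicluster_pvalue <- function(bic, n, m) {
  a <- length(bic$core_rows)
  b <- length(bic$cols)
  exp(min(0, log_submatrix_bound(a, b, n, m)))
}

#' Discover trend-preserving biclusters in an expression matrix
#'
#' Runs the full pipeline: quantile separation and rank granulation
#' ([preprocess_matrix()]), index-matrix construction ([index_matrix()]),
#' partitioned seed search ([compute_k()], [partition_rows()],
#' [generate_seeds()]), and for each seed, longest first, strict growth
#' ([grow_strict()]), column extension ([extend_columns()]), row extension
#' including sign-reversed genes ([extend_rows()]) and significance scoring
#' ([bicluster_pvalue()]).  After each bicluster is formed, seeds whose two
#' rows are both contained in one discovered bicluster are dropped, so
#' overlapping biclusters sharing some rows remain discoverable.  Exact
#' duplicates are removed; blocks with significance at most `alpha` are
#' ranked by increasing p-value (ties: more rows, more columns, discovery
#' order) and the first `o` are returned.
#'
#' @param x numeric expression matrix with row/column names (`NA` allowed),
#'   or a path to a tab-delimited file readable by
#'   [read_expression_matrix()].
#' @param q separation quantile; `NULL` (default) uses `min(0.5, 15/m)`.  Use
#'   `q = 0.5` together with `r = ncol(x)` to take the data as-is.
#' @param r rank count for granulation (default 15).
#' @param alpha significance level for seeding and output filtering.
#' @param col_error column-phase error tolerance (default 0.3).
#' @param row_error row-phase error tolerance (default 0.15).
#' @param o maximum number of biclusters returned (default 100).
#' @param k override for the partition parameter; `NULL` computes it.
#' @param rng_seed integer seed for the row partition shuffle.
#' @return A list of [bicluster()] objects, class `unibic_result`, with
#'   attributes `k`, `threshold`, `n_seeds` and `params`.
#' @examples
#' set.seed(7)
#' x <- make_background(30, 20, rng_seed = 7)
#' x[1:4, 1:6] <- t(replicate(4, sort(rnorm(6))))  # planted pattern
#' res <- unibic(x, q = 0.5, r = ncol(x))
#' res
#' @export
unibic <- function(x, q = NULL, r = 15L, alpha = 0.05, col_error = 0.3,
                   row_error = 0.15, o = 100L, k = NULL, rng_seed = 1L) {
  if (is.character(x) && length(x) == 1L) x <- read_expression_matrix(x)
  validate_expression_matrix(x)
  if (o < 1) stop_param("o must be at least 1")
  n <- nrow(x); m <- ncol(x)
  if (is.null(q)) q <- min(0.5, 15 / m)

  disc <- preprocess_matrix(x, q = q, r = r)
  Y <- index_matrix(disc)
  threshold <- min_significant_length(m, alpha)
  if (is.null(k)) k <- compute_k(n, m, alpha)
  groups <- partition_rows(n, k, rng_seed = rng_seed)
  seeds <- generate_seeds(Y, groups, threshold)

  blocks <- list()
  # seed (a, b) is spent once some single discovered bicluster contains both
  # rows; seeds sharing only one row with a discovered bicluster stay live so
  # overlapping biclusters remain discoverable
  pair_spent <- function(a, b) {
    for (blk in blocks) if (a %in% blk$rows && b %in% blk$rows) return(TRUE)
    FALSE
  }
  for (seed in seeds$seeds) {
    if (pair_spent(seed$row_a, seed$row_b)) next
    blk <- grow_strict(seed, Y)
    if (length(blk$cols) < 3L) next
    bic <- extend_columns(blk, disc, col_error = col_error)
    bic <- extend_rows(bic, Y, row_error = row_error)
    # significance is judged on the strict order-preserving core: the
    # expected-count bound models exact order preservation, and counting
    # error-tolerantly added columns would overstate significance
    bic$p_value <- exp(min(0, log_submatrix_bound(length(blk$rows),
                                                  length(blk$cols), n, m)))
    blocks[[length(blocks) + 1L]] <- bic
  }

  # exact-duplicate removal (same member set, same column set)
  if (length(blocks) > 1L) {
    sig <- vapply(blocks, function(b) {
      paste(paste(sort(b$rows), collapse = ","),
            paste(sort(b$cols), collapse = ","), sep = "|")
    }, "")
    blocks <- blocks[!duplicated(sig)]
  }

  keep <- vapply(blocks, function(b) b$p_value <= alpha, TRUE)
  blocks <- blocks[keep]
  if (length(blocks) > 1L) {
    pv <- vapply(blocks, function(b) b$p_value, 0)
    nr <- vapply(blocks, function(b) length(b$rows), 0L)
    nc <- vapply(blocks, function(b) length(b$cols), 0L)
    blocks <- blocks[order(pv, -nr, -nc, seq_along(blocks))]
  }
  blocks <- head(blocks, o)
  structure(blocks, class = "unibic_result",
            k = k, threshold = threshold, n_seeds = length(seeds$seeds),
            params = list(q = q, r = r, alpha = alpha, col_error = col_error,
                          row_error = row_error, o = o, rng_seed = rng_seed))
}

#' @export
print.unibic_result <- function(x, ...) {
  cat(sprintf("unibic: %d bicluster(s) (k = %d, seed threshold = %d, %d seed(s))\n",
              length(x), attr(x, "k"), attr(x, "threshold"),
              attr(x, "n_seeds")))
  for (i in seq_along(x)) {
    b <- x[[i]]
    cat(sprintf("  BC%03d: %d genes (%d reversed) x %d conditions, p = %.3g\n",
                i, length(b$rows), sum(b$orientation == "-"),
                length(b$cols), b$p_value))
  }
  invisible(x)
}
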