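make_block <- function(rows, cols) {
  structure(list(rows = as.integer(rows), cols = as.integer(cols)),
            class = "unibic_block")
}

test_that("growth absorbs identical rows and stops when nothing retains 3 columns", {
  ident <- c(1, 2, 3, 4, 5, 6)
  x <- rbind(ident, ident, ident,
             c(6, 5, 4, 3, 2, 1),      # reverse: retains nothing useful
             c(5, 6, 3, 4, 1, 2))      # retains at most 2
  Y <- index_matrix(x)
  seed <- list(row_a = 1L, row_b = 2L, sequence = Y[1, ])
  blk <- grow_strict(seed, Y)
  expect_identical(blk$rows, 1:3)
  expect_identical(blk$cols, 1:6)

  # with no extendable third row the two-row seed block comes back unchanged
  Y2 <- Y[c(1, 2, 4, 5), ]
  blk2 <- grow_strict(list(row_a = 1L, row_b = 2L, sequence = Y2[1, ]), Y2)
  expect_identical(blk2$rows, 1:2)
  expect_identical(blk2$cols, 1:6)
})

test_that("growth recovers an implanted strict 5x10 block from any inside pair", {
  x <- make_background(20, 30, rng_seed = 601)
  rows <- c(2, 5, 9, 13, 17)
  set.seed(1)
  cols <- sort(sample(30, 10))
  x <- implant_strict_op(x, rows, cols, rng_seed = 701)
  Y <- index_matrix(preprocess_matrix(x, q = 0.5, r = 30))
  for (pair in list(c(2, 5), c(9, 17), c(5, 13))) {
    sq <- lcs(Y[pair[1], ], Y[pair[2], ])$sequence
    blk <- grow_strict(list(row_a = pair[1], row_b = pair[2], sequence = sq), Y)
    expect_true(all(rows %in% blk$rows))
    expect_gte(sum(cols %in% blk$cols), 8)
    # the grown block is strictly order-preserving in the raw data
    for (g in blk$rows) expect_false(is.unsorted(x[g, blk$cols]))
  }
})

test_that("column extension inserts exactly the consistent column at zero tolerance", {
  disc <- rbind(c(1L, 5L, 3L, 9L), c(2L, 6L, 4L, 0L))
  bic <- extend_columns(make_block(1:2, 1:2), disc, col_error = 0)
  expect_identical(bic$cols, c(1L, 3L, 2L))
  expect_identical(bic$rows, 1:2)
  expect_identical(bic$orientation, c("+", "+"))

  # nothing consistent -> no-op
  disc2 <- rbind(c(1L, 5L, 9L, 0L), c(2L, 6L, 0L, 9L))
  bic2 <- extend_columns(make_block(1:2, 1:2), disc2, col_error = 0)
  expect_identical(bic2$cols, 1:2)
})

test_that("column extension honours the violating-row fraction exactly", {
  # candidate column 3 fits between the consensus for 7 of 10 rows
  disc <- cbind(rep(0L, 10), rep(10L, 10), c(rep(5L, 7), rep(15L, 3)))
  expect_identical(extend_columns(make_block(1:10, 1:2), disc, 0.3)$cols,
                   c(1L, 3L, 2L))
  expect_identical(extend_columns(make_block(1:10, 1:2), disc, 0.2)$cols,
                   1:2)
})

test_that("row extension accepts originals, reversals and enforces the error bound", {
  base <- 1:25
  cand16 <- c(20L, 15L, 10L, 5L, setdiff(1:25, c(20L, 15L, 10L, 5L)))
  Y <- rbind(base, base, rev(base), cand16)
  cons <- 1:20
  bic0 <- bicluster(rows = 1L, cols = cons)
  scan_all <- extend_rows(bic0, Y, row_error = 0)
  expect_identical(scan_all$rows, c(1L, 2L, 3L))
  expect_identical(scan_all$orientation, c("+", "+", "-"))

  # candidate retaining 16 of 20 consensus columns: error 0.2
  expect_false(4L %in% extend_rows(bic0, Y, row_error = 0.15)$rows)
  ext <- extend_rows(bic0, Y, row_error = 0.2)
  expect_true(4L %in% ext$rows)
  expect_identical(ext$orientation[ext$rows == 4L], "+")

  # excluded rows never join
  expect_false(2L %in% extend_rows(bic0, Y, row_error = 0, used = 2L)$rows)
})

test_that("significance bound behaves as documented", {
  # tiny blocks are never significant
  expect_identical(bicluster_pvalue(bicluster(rows = 1:2, cols = 1:2), 20, 20), 1)
  # monotone decreasing in rows and columns
  set.seed(71)
  for (rep in 1:20) {
    n <- sample(20:200, 1); m <- sample(20:100, 1)
    a <- sample(2:(n - 1), 1); b <- sample(3:(m - 1), 1)
    p0 <- bicluster_pvalue(bicluster(rows = 1:a, cols = 1:b), n, m)
    expect_lte(bicluster_pvalue(bicluster(rows = 1:(a + 1), cols = 1:b), n, m), p0)
    expect_lte(bicluster_pvalue(bicluster(rows = 1:a, cols = 1:(b + 1)), n, m), p0)
  }
  # the benchmark-scale 15x15 block is significant, matching a direct
  # factorial evaluation of the expected-count bound
  p <- bicluster_pvalue(bicluster(rows = 1:15, cols = 1:15), 150, 100)
  direct <- prod(86:100) * choose(150, 15) * factorial(15)^-15
  expect_lt(p, 0.05)
  expect_equal(p, direct, tolerance = 1e-9)
})

test_that("a planted strict block dominates the output with correct membership", {
  x <- make_background(40, 30, rng_seed = 81)
  rows <- seq(3, 31, by = 2)
  cols <- sort(sample(30, 15))
  x <- implant_strict_op(x, rows, cols, rng_seed = 82)
  res <- unibic(x, q = 0.5, r = 30)
  expect_gte(length(res), 1)
  expect_gte(jaccard(res[[1]]$rows, rows), 0.9)
})

test_that("pure noise yields no significant biclusters in nearly all replicates", {
  hits <- 0L
  for (rep in 1:20) {
    x <- make_background(50, 50, rng_seed = 900 + rep)
    res <- unibic(x, q = 0.5, r = 50, rng_seed = rep)
    if (length(res) > 0) hits <- hits + 1L
  }
  expect_lte(hits, 1L)  # at most 5% of 20 replicates
})

test_that("an order-reversing companion row joins with reversed orientation", {
  # three genes, seven conditions: two order-preserving rows plus the
  # sign-flip of the first (order-reversing against both)
  ident <- c(2, 9, 4, 11, 6, 13, 8)
  x <- rbind(ident + 0.1, ident + 5, -ident)
  dimnames(x) <- list(paste0("g", 1:3), paste0("c", 1:7))
  res <- unibic(x, q = 0.5, r = 7, rng_seed = 1)
  expect_gte(length(res), 1)
  top <- res[[1]]
  expect_true(all(1:3 %in% top$rows))
  expect_identical(top$orientation[match(3L, top$rows)], "-")
  expect_identical(unique(top$orientation[top$rows %in% 1:2]), "+")
})

test_that("zero-tolerance settings produce exactly trend-preserving output", {
  set.seed(101)
  for (rep in 1:5) {
    x <- make_background(25, 18, rng_seed = 1100 + rep)
    x <- implant_strict_op(x, sample(25, 6), sort(sample(18, 6)),
                           rng_seed = 1200 + rep)
    res <- unibic(x, q = 0.5, r = 18, alpha = 1, col_error = 0,
                  row_error = 0, rng_seed = rep)
    for (b in res) expect_true(bic_exactly_trend_preserving(b, x))
  }
})

test_that("identical inputs and seeds reproduce identical results", {
  x <- make_background(30, 20, rng_seed = 5)
  x <- implant_strict_op(x, 1:6, 1:8, rng_seed = 6)
  r1 <- unibic(x, q = 0.5, r = 20, rng_seed = 99)
  r2 <- unibic(x, q = 0.5, r = 20, rng_seed = 99)
  expect_identical(r1, r2)
})
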