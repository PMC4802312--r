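test_that("backgrounds are standard normal, seeded and distinct across seeds", {
  x <- make_background(300, 200, rng_seed = 42)
  expect_identical(dim(x), c(300L, 200L))
  expect_gt(mean(x), -0.05); expect_lt(mean(x), 0.05)
  expect_gt(var(as.vector(x)), 0.9); expect_lt(var(as.vector(x)), 1.1)
  expect_identical(x, make_background(300, 200, rng_seed = 42))
  expect_false(identical(x, make_background(300, 200, rng_seed = 43)))
})

test_that("trend-preserving implants are pairwise trend-preserving with reversals", {
  x <- make_background(30, 25, rng_seed = 9)
  rows <- 4:15; cols <- 3:14
  spec <- implant_spec("trend_preserving", rows, cols, n_reversed = 4)
  y <- implant(x, spec, rng_seed = 10)
  expect_true(submatrix_trend_preserving(y, rows, cols))
  # exactly 4 rows reverse against the majority orientation
  ords <- apply(y[rows, cols], 1, function(v) paste(order(v), collapse = ","))
  expect_setequal(unname(table(ords)), c(8L, 4L))
  # each row keeps its own sampled values (a permutation of the originals)
  for (r in rows)
    expect_identical(sort(unname(y[r, cols])), sort(unname(x[r, cols])))
  # untouched outside the span
  y[rows, cols] <- x[rows, cols]
  expect_identical(y, x)
})

test_that("constant, shift, scale and shift-scale implants satisfy their algebra", {
  x <- make_background(20, 20, rng_seed = 11)
  rows <- 2:9; cols <- 5:12

  cc <- implant(x, implant_spec("column_constant", rows, cols), rng_seed = 1)
  expect_true(all(apply(cc[rows, cols], 2, function(v) diff(range(v)) == 0)))

  rc <- implant(x, implant_spec("row_constant", rows, cols), rng_seed = 2)
  expect_true(all(apply(rc[rows, cols], 1, function(v) diff(range(v)) == 0)))

  sh <- implant(x, implant_spec("shift", rows, cols), rng_seed = 3)
  d <- sh[rows, cols] - matrix(sh[rows[1], cols], length(rows),
                               length(cols), byrow = TRUE)
  expect_true(all(abs(d - d[, 1]) < 1e-12))

  sc <- implant(x, implant_spec("scale", rows, cols, scale_range = c(2, 2)),
                rng_seed = 4)
  rat <- sc[rows, cols] / matrix(sc[rows[1], cols], length(rows),
                                 length(cols), byrow = TRUE)
  expect_true(all(abs(rat - rat[, 1]) < 1e-10))
  expect_true(all(vapply(seq_along(rows), function(i)
    any(abs(rat[i, 1] - c(0.5, 1, 2)) < 1e-10), TRUE)))

  ss <- implant(x, implant_spec("shift_scale", rows, cols), rng_seed = 5)
  cors <- stats::cor(t(ss[rows, cols]))
  expect_true(all(abs(cors - 1) < 1e-12))  # exact positive affine relations

  expect_error(implant(x, implant_spec("shift", 15:25, cols), rng_seed = 1),
               "span")
})

test_that("non-overlapping scenarios implant disjoint spans of the stated sizes", {
  gen <- generate_scenario("sixtypes_c", "trend_preserving", replicate = 1,
                           rng_seed = 5)
  expect_identical(dim(gen$matrix), c(300L, 200L))
  tb <- gen$truth$biclusters
  expect_length(tb, 5)
  for (b in tb) {
    expect_length(b$rows, 25)
    expect_length(b$cols, 25)
  }
  for (i in 1:4) for (j in (i + 1):5) {
    expect_length(intersect(tb[[i]]$rows, tb[[j]]$rows), 0)
    expect_length(intersect(tb[[i]]$cols, tb[[j]]$cols), 0)
  }
  for (b in tb) expect_true(submatrix_trend_preserving(gen$matrix, b$rows, b$cols))
})

test_that("overlap scenarios chain consecutive implants by exactly d x d", {
  for (d in c(0L, 9L)) {
    gen <- generate_scenario(paste0("overlap_", d), replicate = 2, rng_seed = 3)
    tb <- gen$truth$biclusters
    expect_length(tb, 3)
    for (i in 1:2) {
      expect_length(intersect(tb[[i]]$rows, tb[[i + 1]]$rows), d)
      expect_length(intersect(tb[[i]]$cols, tb[[i + 1]]$cols), d)
    }
    expect_length(intersect(tb[[1]]$rows, tb[[3]]$rows), 0)
    # the last implant is exactly trend-preserving even after shifting;
    # earlier implants are exact outside the overwritten corner
    expect_true(submatrix_trend_preserving(gen$matrix, tb[[3]]$rows, tb[[3]]$cols))
    keep1 <- setdiff(tb[[1]]$rows, tb[[2]]$rows)
    expect_true(submatrix_trend_preserving(gen$matrix, keep1, tb[[1]]$cols))
    if (d == 0)
      expect_true(submatrix_trend_preserving(gen$matrix, tb[[1]]$rows, tb[[1]]$cols))
  }
})

test_that("scenario replicates differ and identical calls reproduce", {
  g1 <- generate_scenario("sixtypes_a", "shift", replicate = 1, rng_seed = 1)
  g2 <- generate_scenario("sixtypes_a", "shift", replicate = 2, rng_seed = 1)
  g1b <- generate_scenario("sixtypes_a", "shift", replicate = 1, rng_seed = 1)
  expect_false(identical(g1$matrix, g2$matrix))
  expect_identical(g1, g1b)
  expect_error(generate_scenario("nope"), "unknown scenario")
})

test_that("ground truth round-trips through JSON", {
  gen <- generate_scenario("overlap_3", replicate = 1, rng_seed = 8)
  tf <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(gen$truth, tf)
  back <- read_ground_truth(tf)
  expect_equal(back$shape, gen$truth$shape)
  expect_identical(length(back$biclusters), length(gen$truth$biclusters))
  for (i in seq_along(back$biclusters)) {
    expect_identical(back$biclusters[[i]]$rows, gen$truth$biclusters[[i]]$rows)
    expect_identical(back$biclusters[[i]]$cols, gen$truth$biclusters[[i]]$cols)
    expect_identical(back$biclusters[[i]]$type, gen$truth$biclusters[[i]]$type)
  }
})
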