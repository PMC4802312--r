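#' Gaussian background matrix
#'
#' An `n x m` matrix of i.i.d. standard normal entries, deterministic given
#' the seed, with gene ids `g1..gn` and condition names `c1..cm`.
#'
#' @param n,m dimensions.
#' @param rng_seed integer seed.
#' @return A numeric matrix.
#' @export
make_background <- function(n, m, rng_seed = 1L) {
  if (n < 1 || m < 1) stop_param("n and m must be positive")
  x <- withr::with_seed(rng_seed, matrix(rnorm(n * m), n, m))
  dimnames(x) <- list(paste0("g", seq_len(n)), paste0("c", seq_len(m)))
  x
}

#' Specification of one implanted bicluster
#'
#' @param type one of `"trend_preserving"`, `"column_constant"`,
#'   `"row_constant"`, `"shift_scale"`, `"shift"`, `"scale"`.
#' @param rows,cols integer index ranges of the submatrix to overwrite.
#' @param n_reversed for `"trend_preserving"`, how many non-base rows are made
#'   order-reversing versus the base row.
#' @param shift_range,scale_range ranges for the per-row shift and (positive)
#'   scale coefficients of the affine types.
#' @return A list of class `unibic_implant_spec`.
#' @export
implant_spec <- function(type = c("trend_preserving", "column_constant",
                                  "row_constant", "shift_scale", "shift",
                                  "scale"),
                         rows, cols, n_reversed = 0L,
                         shift_range = c(-5, 5), scale_range = c(0.5, 3)) {
  type <- match.arg(type)
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (anyDuplicated(rows) || anyDuplicated(cols))
    stop_param("implant spans must not repeat indices")
  if (n_reversed >= length(rows))
    stop_param("n_reversed must leave at least the base row unreversed")
  if (any(scale_range <= 0))
    stop_param("scales must be positive")
  structure(list(type = type, rows = rows, cols = cols,
                 n_reversed = as.integer(n_reversed),
                 shift_range = shift_range, scale_range = scale_range),
            class = "unibic_implant_spec")
}

#' Overwrite a submatrix with a patterned bicluster
#'
#' Modifies only the spanned submatrix, according to the spec's type:
#' \describe{
#'   \item{trend_preserving}{a random base row is chosen; every other row's
#'     own entries are rearranged so its within-row rank order matches the
#'     base row's (each row keeps its sampled values); `n_reversed` randomly
#'     chosen non-base rows get the reversed rank order instead.}
#'   \item{column_constant}{one random row of the span is copied to all rows.}
#'   \item{row_constant}{one random column of the span is copied to all
#'     columns.}
#'   \item{shift_scale}{other rows become `shift + scale * base` with per-row
#'     random coefficients.}
#'   \item{shift}{as `shift_scale` with `scale = 1`.}
#'   \item{scale}{as `shift_scale` with `shift = 0`.}
#' }
#'
#' @param x numeric matrix to modify.
#' @param spec an [implant_spec()].
#' @param rng_seed integer seed for the choices above.
#' @return The modified matrix.
#' @export
implant <- function(x, spec, rng_seed = 1L) {
  if (!inherits(spec, "unibic_implant_spec"))
    stop_param("spec must come from implant_spec()")
  if (any(spec$rows < 1L | spec$rows > nrow(x)) ||
      any(spec$cols < 1L | spec$cols > ncol(x)))
    stop_validation("implant span exceeds the matrix")
  R <- spec$rows; C <- spec$cols
  nr <- length(R); nc <- length(C)
  withr::with_seed(rng_seed, {
    base <- sample.int(nr, 1L)
    sub <- x[R, C, drop = FALSE]
    if (spec$type == "trend_preserving") {
      perm <- order(sub[base, ])
      reversed <- sample(setdiff(seq_len(nr), base),
                         min(spec$n_reversed, nr - 1L))
      for (i in seq_len(nr)) {
        if (i == base) next
        vals <- sort(sub[i, ])
        if (i %in% reversed) vals <- rev(vals)
        sub[i, perm] <- vals
      }
    } else if (spec$type == "column_constant") {
      sub <- matrix(sub[base, ], nr, nc, byrow = TRUE)
    } else if (spec$type == "row_constant") {
      bc <- sample.int(nc, 1L)
      sub <- matrix(sub[, bc], nr, nc)
    } else {
      shifts <- runif(nr, spec$shift_range[1L], spec$shift_range[2L])
      scales <- runif(nr, spec$scale_range[1L], spec$scale_range[2L])
      if (spec$type == "shift") scales[] <- 1
      if (spec$type == "scale") shifts[] <- 0
      for (i in seq_len(nr)) {
        if (i == base) next
        sub[i, ] <- shifts[i] + scales[i] * sub[base, ]
      }
    }
    x[R, C] <- sub
  })
  x
}

# uniformly chosen pairwise-disjoint intervals of length len in 1..n,
# returned as a list of index vectors (classic stars-and-bars mapping)
disjoint_spans <- function(n, count, len) {
  slots <- n - count * (len - 1L)
  if (slots < count) stop_param("spans do not fit")
  picks <- sort(sample.int(slots, count))
  lapply(seq_len(count), function(i) {
    start <- picks[i] + (i - 1L) * (len - 1L)
    start:(start + len - 1L)
  })
}

scenario_table <- function() {
  list(
    sixtypes_a = list(shape = c(150L, 100L), n_bic = 3L, size = 15L, overlap = NA),
    sixtypes_b = list(shape = c(200L, 150L), n_bic = 4L, size = 20L, overlap = NA),
    sixtypes_c = list(shape = c(300L, 200L), n_bic = 5L, size = 25L, overlap = NA),
    overlap_0 = list(shape = c(200L, 150L), n_bic = 3L, size = 20L, overlap = 0L),
    overlap_3 = list(shape = c(200L, 150L), n_bic = 3L, size = 20L, overlap = 3L),
    overlap_6 = list(shape = c(200L, 150L), n_bic = 3L, size = 20L, overlap = 6L),
    overlap_9 = list(shape = c(200L, 150L), n_bic = 3L, size = 20L, overlap = 9L))
}

#' Generate one synthetic benchmark matrix with ground truth
#'
#' The non-overlapping scenarios implant biclusters of one of the six types
#' into a Gaussian background at uniformly chosen pairwise-disjoint row and
#' column spans: `sixtypes_a` is 150 x 100 with three 15 x 15 implants,
#' `sixtypes_b` 200 x 150 with four 20 x 20, `sixtypes_c` 300 x 200 with five
#' 25 x 25.  Trend-preserving implants make 5 rows order-reversing.  The
#' `overlap_d` scenarios (`d` in 0, 3, 6, 9) implant three 20 x 20
#' trend-preserving biclusters into a 200 x 150 background so that
#' consecutive implants share exactly a `d x d` submatrix (later implants
#' overwrite the shared corner), with the three blocks shifted by the
#' constants 2, 4 and 6.
#'
#' @param name scenario id, one of `sixtypes_a`, `sixtypes_b`, `sixtypes_c`,
#'   `overlap_0`, `overlap_3`, `overlap_6`, `overlap_9`.
#' @param type implant type (see [implant_spec()]); overlap scenarios always
#'   use `trend_preserving`.
#' @param replicate replicate index; distinct replicates give distinct
#'   matrices.
#' @param rng_seed base integer seed.
#' @return A list with `matrix` and `truth` (class `unibic_ground_truth`:
#'   `shape`, `seed`, and a `biclusters` list of `(rows, cols, type)`).
#' @export
generate_scenario <- function(name, type = "trend_preserving",
                              replicate = 1L, rng_seed = 1L) {
  tab <- scenario_table()
  if (!name %in% names(tab))
    stop_param("unknown scenario '", name, "'; use one of: ",
               paste(names(tab), collapse = ", "))
  sc <- tab[[name]]
  overlap_mode <- !is.na(sc$overlap)
  if (overlap_mode) type <- "trend_preserving"
  type <- match.arg(type, c("trend_preserving", "column_constant",
                            "row_constant", "shift_scale", "shift", "scale"))
  seed0 <- derive_seed(rng_seed, match(name, names(tab)),
                       match(type, c("trend_preserving", "column_constant",
                                     "row_constant", "shift_scale", "shift",
                                     "scale")),
                       replicate)
  n <- sc$shape[1L]; m <- sc$shape[2L]
  x <- make_background(n, m, rng_seed = seed0)
  L <- sc$size
  nb <- sc$n_bic
  if (overlap_mode) {
    d <- sc$overlap
    step <- L - d
    chain <- L + (nb - 1L) * step  # rows/cols covered by the chained blocks
    offs <- withr::with_seed(derive_seed(seed0, 1L), {
      c(sample.int(n - chain + 1L, 1L), sample.int(m - chain + 1L, 1L))
    })
    row_spans <- lapply(seq_len(nb) - 1L,
                        function(i) (offs[1L] + i * step):(offs[1L] + i * step + L - 1L))
    col_spans <- lapply(seq_len(nb) - 1L,
                        function(i) (offs[2L] + i * step):(offs[2L] + i * step + L - 1L))
  } else {
    spans <- withr::with_seed(derive_seed(seed0, 1L), {
      list(rows = disjoint_spans(n, nb, L), cols = disjoint_spans(m, nb, L))
    })
    row_spans <- spans$rows
    col_spans <- spans$cols
  }
  truth <- vector("list", nb)
  for (i in seq_len(nb)) {
    spec <- implant_spec(type, rows = row_spans[[i]], cols = col_spans[[i]],
                         n_reversed = if (type == "trend_preserving") 5L else 0L)
    x <- implant(x, spec, rng_seed = derive_seed(seed0, 100L + i))
    if (overlap_mode) x[row_spans[[i]], col_spans[[i]]] <-
        x[row_spans[[i]], col_spans[[i]]] + 2 * i
    truth[[i]] <- list(rows = row_spans[[i]], cols = col_spans[[i]],
                       type = type)
  }
  list(matrix = x,
       truth = structure(list(shape = c(n, m), seed = seed0,
                              biclusters = truth),
                         class = "unibic_ground_truth"))
}

#' Write ground truth to JSON
#' @param truth a `unibic_ground_truth`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(
    list(shape = truth$shape, seed = truth$seed,
         biclusters = lapply(truth$biclusters, function(b)
           list(rows = b$rows, cols = b$cols, type = b$type))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read ground truth from JSON
#' @param path path written by [write_ground_truth()].
#' @return A `unibic_ground_truth`.
#' @export
read_ground_truth <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  structure(list(shape = as.integer(j$shape), seed = j$seed,
                 biclusters = lapply(j$biclusters, function(b)
                   list(rows = as.integer(b$rows), cols = as.integer(b$cols),
                        type = b$type))),
            class = "unibic_ground_truth")
}
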