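#' Separate up- and down-regulated entries from the background
#'
#' Per gene row, values far from the row median are flagged as up- or
#' down-regulated and everything else is zeroed.  With the row's non-missing
#' values sorted ascending as \eqn{a_{(1)} \le \dots \le a_{(m')}}, the anchor
#' positions are \eqn{s = \lfloor q m' \rfloor} (clamped to at least 1),
#' \eqn{l = \lfloor m'/2 \rfloor} and \eqn{t = \lfloor (1-q) m' \rfloor}
#' (clamped to at most \eqn{m'}), and the half-width is
#' \eqn{d = \min(a_{(l)} - a_{(s)},\; a_{(t)} - a_{(l)})}.  Entries strictly
#' above \eqn{a_{(l)} + d} are up-regulated, entries strictly below
#' \eqn{a_{(l)} - d} are down-regulated.  Missing entries are always zeroed
#' (treated as inactive).  `q = 0.5` makes `d = 0`, so every entry except the
#' row median survives with its sign: the mode used when the data should be
#' taken as-is.
#'
#' @param x numeric expression matrix (may contain `NA`).
#' @param q separation quantile, a fraction in (0, 0.5].
#' @return A list of class `unibic_separation`: `thresholded` (the matrix with
#'   non-selected entries zeroed), logical `up_mask` and `down_mask`, and a
#'   per-row `diagnostics` data frame with columns `a_is`, `a_il`, `a_it`, `d`.
#' @export
separate_expression <- function(x, q) {
  if (!is.numeric(q) || length(q) != 1L || !is.finite(q) || q <= 0 || q > 0.5)
    stop_param("q must be a single value in (0, 0.5], got ", q)
  validate_expression_matrix(x)
  n <- nrow(x); m <- ncol(x)
  up <- down <- matrix(FALSE, n, m, dimnames = dimnames(x))
  diag_df <- data.frame(a_is = rep(NA_real_, n), a_il = NA_real_,
                        a_it = NA_real_, d = NA_real_,
                        row.names = rownames(x))
  for (i in seq_len(n)) {
    v <- x[i, ]
    ok <- !is.na(v)
    me <- sum(ok)
    if (me < 2L) next
    sorted <- sort(v[ok])
    s <- max(1L, floor(q * me))
    l <- max(1L, floor(me / 2))
    t <- min(me, floor((1 - q) * me))
    d <- min(sorted[l] - sorted[s], sorted[t] - sorted[l])
    up[i, ] <- ok & v > sorted[l] + d
    down[i, ] <- ok & v < sorted[l] - d
    diag_df[i, ] <- c(sorted[s], sorted[l], sorted[t], d)
  }
  thr <- x
  thr[!(up | down)] <- 0
  thr[is.na(thr)] <- 0
  structure(list(thresholded = thr, up_mask = up, down_mask = down,
                 diagnostics = diag_df, q = q),
            class = "unibic_separation")
}

# equal-count ranks 1..r for values already known to be on one side of the
# separation; ties always share a rank, and larger values never rank lower
rank_bins <- function(values, r) {
  nv <- length(values)
  if (nv == 0L) return(integer(0))
  ord <- order(values)
  prelim <- ceiling(seq_len(nv) * r / nv)
  # ties: every entry of a tied run takes the run's largest preliminary rank
  sorted <- values[ord]
  grp <- cumsum(c(TRUE, sorted[-1L] != sorted[-nv]))
  per_grp <- tapply(prelim, grp, max)
  out <- integer(nv)
  out[ord] <- as.integer(per_grp[grp])
  out
}

#' Granulate separated values into integer ranks
#'
#' Within each row, up-regulated entries are binned by value into `r`
#' equal-count intervals and replaced by integers 1..`r` with larger values
#' receiving larger integers; down-regulated entries symmetrically receive
#' -1..-`r`, the most negative values mapping to -`r`.  Rows with fewer than
#' `r` selected entries spread their distinct values over the available ranks
#' while preserving order.  Zeros (inactive entries) pass through unchanged.
#'
#' @param sep a `unibic_separation` from [separate_expression()].
#' @param r positive integer rank count.
#' @return An integer matrix with entries in `-r..r` and attribute
#'   `rank_count`.
#' @export
granulate <- function(sep, r) {
  if (!inherits(sep, "unibic_separation"))
    stop_param("sep must come from separate_expression()")
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r < 1)
    stop_param("r must be a positive integer, got ", r)
  r <- as.integer(r)
  n <- nrow(sep$thresholded)
  out <- matrix(0L, n, ncol(sep$thresholded),
                dimnames = dimnames(sep$thresholded))
  for (i in seq_len(n)) {
    u <- sep$up_mask[i, ]
    dn <- sep$down_mask[i, ]
    if (any(u)) out[i, u] <- rank_bins(sep$thresholded[i, u], r)
    if (any(dn)) out[i, dn] <- -rank_bins(-sep$thresholded[i, dn], r)
  }
  attr(out, "rank_count") <- r
  out
}

#' Preprocess an expression matrix into an integer rank matrix
#'
#' Composition of [separate_expression()] and [granulate()].  The default `q`
#' is `15/m` (clamped to 0.5 for narrow matrices).  Running with `q = 0.5` and
#' `r = m` skips any effective preprocessing: within each row the nonzero
#' integer ranks are then ordered exactly as the raw values.
#'
#' @param x numeric expression matrix.
#' @param q separation quantile; `NULL` for the default `min(0.5, 15/m)`.
#' @param r rank count (default 15).
#' @return Integer matrix as from [granulate()].
#' @export
preprocess_matrix <- function(x, q = NULL, r = 15L) {
  validate_expression_matrix(x)
  if (is.null(q)) q <- min(0.5, 15 / ncol(x))
  granulate(separate_expression(x, q), r)
}
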