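#' Read a tab-delimited expression matrix
#'
#' Parses the conventional text format for gene expression data: a header line
#' of condition names followed by one line per gene, each holding the gene
#' identifier and one numeric token per condition.  Empty tokens, `NA` and
#' `NaN` (case-insensitive) mark missing measurements and become `NA` entries.
#' A header carrying one extra leading token (a corner label above the gene id
#' column) is tolerated and the token dropped.
#'
#' @param path path to a tab-delimited text file.
#' @return A numeric matrix with gene identifiers as row names and condition
#'   names as column names; missing entries are `NA`.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("c1\tc2", "g1\t1.0\t2.0", "g2\t4.0\t3.0"), tf)
#' read_expression_matrix(tf)
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) | seq_along(lines) == 1L]
  if (length(lines) < 3L)
    stop_validation("need a header and at least 2 gene rows, got ",
                    length(lines) - 1L, " data line(s)")
  toks <- strsplit(lines, "\t", fixed = TRUE)
  header <- toks[[1L]]
  body <- toks[-1L]
  widths <- lengths(body)
  m <- widths[1L] - 1L
  if (length(header) == m + 1L) header <- header[-1L]
  if (length(header) != m)
    stop_format("header has ", length(header),
                " condition names but line 2 carries ", m, " values")
  if (m < 2L) stop_validation("fewer than 2 columns")
  bad <- which(widths != m + 1L)
  if (length(bad))
    stop_format("ragged row: line ", bad[1L] + 1L, " has ", widths[bad[1L]],
                " fields, expected ", m + 1L)
  ids <- vapply(body, `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop_validation("duplicate gene id: ", ids[duplicated(ids)][1L])
  raw <- unlist(lapply(body, `[`, -1L), use.names = FALSE)
  missing <- raw == "" | tolower(raw) %in% c("na", "nan")
  vals <- suppressWarnings(as.numeric(raw))
  vals[missing] <- NA_real_
  bad_tok <- which(!missing & !is.finite(vals))
  if (length(bad_tok)) {
    line <- (bad_tok[1L] - 1L) %/% m + 2L
    stop_format("non-numeric value '", raw[bad_tok[1L]], "' on line ", line)
  }
  x <- matrix(vals, nrow = length(body), ncol = m, byrow = TRUE,
              dimnames = list(ids, header))
  validate_expression_matrix(x)
  x
}

#' Write an expression matrix as tab-delimited text
#'
#' @param x numeric matrix with row and column names.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  validate_expression_matrix(x)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(colnames(x), collapse = "\t"), con)
  body <- apply(x, 1L, function(v) {
    paste(ifelse(is.na(v), "NA", format(v, digits = 17, trim = TRUE,
                                        scientific = FALSE)),
          collapse = "\t")
  })
  writeLines(paste(rownames(x), body, sep = "\t"), con)
  invisible(path)
}

validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop_validation("expression data must be a numeric matrix")
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop_validation("need at least 2 rows and 2 columns, got ",
                    nrow(x), "x", ncol(x))
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop_validation("expression matrix needs row and column names")
  if (anyDuplicated(rownames(x)))
    stop_validation("duplicate gene id: ",
                    rownames(x)[duplicated(rownames(x))][1L])
  if (anyDuplicated(colnames(x)))
    stop_validation("duplicate condition name: ",
                    colnames(x)[duplicated(colnames(x))][1L])
  if (any(is.infinite(x)))
    stop_validation("non-finite values present; use NA for missing entries")
  invisible(x)
}

#' Construct a bicluster object
#'
#' A bicluster holds member gene rows, each flagged as original (`"+"`) or
#' sign-reversed (`"-"`), an ordered consensus sequence of condition columns
#' (increasing-expression order for original members), a significance value,
#' and the subset of members that form the strict order-preserving core.
#'
#' @param rows integer vector of member row indices.
#' @param orientation character vector, `"+"` or `"-"` per member.
#' @param cols integer vector of condition column indices in consensus order.
#' @param p_value significance value in \[0, 1\].
#' @param core_rows subset of `rows` forming the strict core.
#' @return An object of class `unibic_bicluster`.
#' @export
bicluster <- function(rows, orientation = rep("+", length(rows)), cols,
                      p_value = NA_real_, core_rows = rows) {
  rows <- as.integer(rows)
  cols <- as.integer(cols)
  if (length(rows) == 0L || length(cols) == 0L)
    stop_validation("bicluster needs at least one row and one column")
  if (anyDuplicated(rows)) stop_validation("duplicate row in bicluster")
  if (anyDuplicated(cols)) stop_validation("duplicate column in bicluster")
  if (length(orientation) != length(rows) ||
      !all(orientation %in% c("+", "-")))
    stop_validation("orientation must be '+' or '-' per member row")
  structure(list(rows = rows, orientation = orientation, cols = cols,
                 p_value = as.numeric(p_value),
                 core_rows = as.integer(core_rows)),
            class = "unibic_bicluster")
}

#' @export
print.unibic_bicluster <- function(x, ...) {
  cat(sprintf("bicluster: %d genes (%d reversed) x %d conditions, p = %.3g\n",
              length(x$rows), sum(x$orientation == "-"), length(x$cols),
              x$p_value))
  invisible(x)
}

#' Write biclusters as annotated text blocks plus a JSON sidecar
#'
#' The text file holds one human-readable block per bicluster (`BC### |
#' pvalue=...`, a `Genes [k]:` line where each id carries a `+`/`-` orientation
#' suffix, and a `Conds [s]:` line in consensus order).  A machine-readable
#' JSON sidecar is written next to it at `<path>.json`; [read_biclusters()]
#' restores the structures losslessly from the sidecar.  Serialized output
#' refers to genes and conditions by name, never by index.
#'
#' @param bics list of [bicluster()] objects.
#' @param x the expression matrix the indices refer to.
#' @param path output path for the text file.
#' @return `path`, invisibly.
#' @export
write_biclusters <- function(bics, x, path) {
  validate_expression_matrix(x)
  for (b in bics) {
    if (any(b$rows < 1L | b$rows > nrow(x)) ||
        any(b$cols < 1L | b$cols > ncol(x)))
      stop_validation("bicluster index out of range for a ",
                      nrow(x), "x", ncol(x), " matrix")
  }
  con <- file(path, open = "wt")
  writeLines(sprintf("# %d bicluster(s)", length(bics)), con)
  for (i in seq_along(bics)) {
    b <- bics[[i]]
    writeLines(c(
      sprintf("BC%03d | pvalue=%.6g", i, b$p_value),
      sprintf("Genes [%d]: %s", length(b$rows),
              paste0(rownames(x)[b$rows], b$orientation, collapse = " ")),
      sprintf("Conds [%d]: %s", length(b$cols),
              paste(colnames(x)[b$cols], collapse = " "))), con)
  }
  close(con)
  side <- lapply(seq_along(bics), function(i) {
    b <- bics[[i]]
    list(id = i,
         genes = data.frame(name = rownames(x)[b$rows],
                            orientation = b$orientation),
         conditions = colnames(x)[b$cols],
         p_value = b$p_value)
  })
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read biclusters back from a JSON sidecar
#'
#' @param path path to the `.json` sidecar (or to the text file written by
#'   [write_biclusters()], in which case `.json` is appended).
#' @param x optional expression matrix; when given, gene and condition names
#'   are mapped back to row/column indices and full [bicluster()] objects are
#'   returned.  Without it, names are kept as character vectors.
#' @return A list, one element per bicluster.
#' @export
read_biclusters <- function(path, x = NULL) {
  if (!grepl("\\.json$", path)) path <- paste0(path, ".json")
  side <- jsonlite::read_json(path, simplifyVector = TRUE,
                              simplifyDataFrame = TRUE)
  if (length(side) == 0L) return(list())
  out <- lapply(seq_len(nrow(side)), function(i) {
    genes <- side$genes[[i]]
    list(genes = genes$name, orientation = genes$orientation,
         conditions = unlist(side$conditions[i]),
         p_value = side$p_value[i])
  })
  if (is.null(x)) return(out)
  validate_expression_matrix(x)
  lapply(out, function(b) {
    rows <- match(b$genes, rownames(x))
    cols <- match(b$conditions, colnames(x))
    if (anyNA(rows) || anyNA(cols))
      stop_validation("bicluster refers to genes/conditions absent from the matrix")
    bicluster(rows = rows, orientation = b$orientation, cols = cols,
              p_value = b$p_value)
  })
}
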