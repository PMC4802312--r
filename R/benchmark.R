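#' Run the synthetic benchmark end to end
#'
#' For every combination of scenario, implant type and replicate: generate
#' the matrix with [generate_scenario()], run [unibic()] with `q = 0.5` and
#' `r = m` (the take-data-as-is mode appropriate for noiseless synthetic
#' implants), and score with [relevance_recovery()].  Per-run rows and
#' per-type means with standard errors are returned; everything is
#' deterministic given `rng_seed`.
#'
#' @param scenarios character vector of scenario ids (see
#'   [generate_scenario()]).
#' @param types character vector of implant types.
#' @param replicates integer vector of replicate indices (default `1:5`).
#' @param rng_seed base integer seed.
#' @param alpha,col_error,row_error,o passed to [unibic()].
#' @return A list of class `unibic_benchmark` with data frames `runs`
#'   (scenario, type, replicate, n_found, relevance, recovery) and `summary`
#'   (per-type means and standard errors over all runs of that type).
#' @export
run_benchmark <- function(scenarios, types = "trend_preserving",
                          replicates = 1:5, rng_seed = 1L, alpha = 0.05,
                          col_error = 0.3, row_error = 0.15, o = 100L) {
  grid <- expand.grid(replicate = as.integer(replicates),
                      scenario = scenarios, type = types,
                      stringsAsFactors = FALSE)
  grid <- grid[, c("scenario", "type", "replicate")]
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    gen <- generate_scenario(g$scenario, type = g$type,
                             replicate = g$replicate, rng_seed = rng_seed)
    res <- unibic(gen$matrix, q = 0.5, r = ncol(gen$matrix), alpha = alpha,
                  col_error = col_error, row_error = row_error, o = o,
                  rng_seed = derive_seed(rng_seed, 7L, i))
    rr <- relevance_recovery(gen$truth, res)
    rows[[i]] <- data.frame(scenario = g$scenario, type = g$type,
                            replicate = g$replicate,
                            n_found = length(res),
                            relevance = rr[["relevance"]],
                            recovery = rr[["recovery"]])
  }
  runs <- do.call(rbind, rows)
  rownames(runs) <- NULL
  summ <- do.call(rbind, lapply(unique(runs$type), function(ty) {
    sub <- runs[runs$type == ty, ]
    data.frame(type = ty, n_runs = nrow(sub),
               relevance_mean = mean(sub$relevance),
               relevance_se = se_mean(sub$relevance),
               recovery_mean = mean(sub$recovery),
               recovery_se = se_mean(sub$recovery))
  }))
  rownames(summ) <- NULL
  structure(list(runs = runs, summary = summ, rng_seed = rng_seed),
            class = "unibic_benchmark")
}

#' @export
print.unibic_benchmark <- function(x, ...) {
  cat(sprintf("benchmark: %d run(s)\n", nrow(x$runs)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write a benchmark as a tab-separated table
#'
#' One TSV with a `kind` column: `run` rows carry per-run scores, `mean` rows
#' carry per-type means and standard errors.  Repeated calls on the same
#' benchmark object produce byte-identical files.
#'
#' @param bench a `unibic_benchmark`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_benchmark_tsv <- function(bench, path) {
  runs <- cbind(kind = "run", bench$runs,
                relevance_se = NA_real_, recovery_se = NA_real_)
  means <- data.frame(kind = "mean", scenario = "all",
                      type = bench$summary$type, replicate = NA_integer_,
                      n_found = NA_integer_,
                      relevance = bench$summary$relevance_mean,
                      recovery = bench$summary$recovery_mean,
                      relevance_se = bench$summary$relevance_se,
                      recovery_se = bench$summary$recovery_se)
  tab <- rbind(runs, means)
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], function(v)
    ifelse(is.na(v), "NA", sprintf("%.10g", v)))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
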