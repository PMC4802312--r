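# unibic

Trend-preserving biclustering of gene expression matrices.

Genes co-regulated under a subset of conditions show coherent *trends*
there, not necessarily similar values: their expression vectors over those
conditions are **order-preserving** (same within-row rank order) or
**order-reversing** (rank order of one matches the negation of the other).
A **trend-preserving bicluster** — a gene set x condition set in which every
gene pair is one or the other — generalizes the constant, shift, scale and
shift-scale bicluster families, and is the structure this package searches
for.

The search reduces biclustering to longest-common-subsequence (LCS)
computations.  For each gene build its **index row**: the permutation of
condition indices sorted by increasing expression (ties toward the smaller
column index).  Genes `i` and `j` admit an order-preserving bicluster over
columns `S` exactly when `S` is a common subsequence of their index rows, so
a significant LCS between two index rows *seeds* a bicluster.  Each seed is
grown greedily into a strict order-preserving block, extended with
error-tolerant columns (violation fraction <= `col_error`) and rows —
original or sign-reversed (consensus retention >= `1 - row_error`) — and
scored by the expected count of equally large strict blocks in a random
matrix,

    U(a, b) = [m!/(m-b)!] * C(n, a) * (1/b!)^a ,

with blocks kept at `U <= alpha`.  Raw data are first separated into up-,
down-regulated and inactive entries by a per-row quantile rule (`q`) and
granulated into integer ranks (`r`); running with `q = 0.5, r = m` takes the
matrix as-is.

## Worked example

Generate a 150x100 standard-normal matrix with three implanted 15x15
trend-preserving biclusters (5 order-reversing rows each), recover them, and
score the result:

```r
library(unibic)
gen <- generate_scenario("sixtypes_a", type = "trend_preserving",
                         replicate = 1, rng_seed = 1)
res <- unibic(gen$matrix, q = 0.5, r = ncol(gen$matrix))
res
#> unibic: 4 bicluster(s) (k = 1, seed threshold = 20, 713 seed(s))
#>   BC001: 15 genes (5 reversed) x 15 conditions, p = 1.78e-67
#>   BC002: 15 genes (5 reversed) x 15 conditions, p = 5.91e-58
#>   BC003: 15 genes (5 reversed) x 15 conditions, p = 9.25e-49
#>   BC004: 16 genes (5 reversed) x 15 conditions, p = 1.27e-05
relevance_recovery(gen$truth, res)
#> relevance  recovery
#>  0.984375  1.000000
```

All three implants come back exactly (recovery 1): 15 genes each, with the
5 anti-correlated genes flagged as reversed, at vanishing p-values.  The
fourth block is a rediscovery of one implant dragged one extra gene by a
chance seed; it costs a little relevance (0.98) and ranks last.  `unibic()`
accepts a matrix or a path to a tab-delimited file (header of condition
names, one gene per line, `NA` for missing); results serialize with
`write_biclusters()` to annotated text plus a JSON sidecar.

A command-line front-end wrapping the same functions ships at
`inst/cli/unibic.R` with `run`, `simulate`, `evaluate` and `benchmark`
subcommands, e.g.

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "unibic.R", package = "unibic"))')" \
  run -i matrix.tsv --no-preprocess --seed 1 -O out
```

See `vignettes/trend-preserving-biclustering.Rmd` for the model,
significance calibration, parameter guidance and design rationale.

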