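# Small in-code fixtures shared across test files.

# Gaussian class structure directly on the log2 scale (bypasses the count
# path) -- fast input for classifier-level tests. Genes in rows.
make_classes <- function(D = 200, sizes = c(20, 20), effect = 3,
                         noise = 1, markers = 15, seed = 1) {
  stopifnot(markers * length(sizes) <= D)
  withr_seed <- function(s, expr) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(s); expr
  }
  withr_seed(seed, {
    N <- sum(sizes)
    y <- rep(sprintf("cl%02d", seq_along(sizes)), sizes)
    base <- rnorm(D, 4, 1)
    x <- matrix(base, D, N) + matrix(rnorm(D * N, 0, noise), D, N)
    for (ci in seq_along(sizes)) {
      rows <- ((ci - 1) * markers + 1):(ci * markers)
      x[rows, y == sprintf("cl%02d", ci)] <-
        x[rows, y == sprintf("cl%02d", ci)] + effect
    }
    x <- pmax(x, 0)
    dimnames(x) <- list(sprintf("G%04d", seq_len(D)), sprintf("S%03d", seq_len(N)))
    list(x = x, y = setNames(y, colnames(x)))
  })
}

# Gaussian cluster data (samples in columns) for distance-preservation
# checks: a mixture with separated centers so pairwise distances span a
# wide range, as cohort expression data does.
gaussian_clusters <- function(N = 100, D = 2000, k = 5, center_sd = 2,
                              seed = 1) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  cl <- sample(rep(seq_len(k), length.out = N))
  centers <- matrix(rnorm(k * D, 0, center_sd), k, D)
  x <- t(centers[cl, , drop = FALSE] + matrix(rnorm(N * D), N, D))
  dimnames(x) <- list(sprintf("G%04d", seq_len(D)), sprintf("S%03d", seq_len(N)))
  list(x = x, cluster = cl)
}

# Write a small delimited expression table to a temp file.
write_expr_file <- function(m, sep = "\t", ext = if (sep == ",") ".csv" else ".tsv") {
  path <- tempfile(fileext = ext)
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}
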