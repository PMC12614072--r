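#' Very sparse random projection matrix
#'
#' Draws a `d` x `D` projection matrix `R` with i.i.d. entries taking the
#' value `+sqrt(p)` with probability `1/(2p)`, `0` with probability
#' `1 - 1/p`, and `-sqrt(p)` with probability `1/(2p)`. The entries have
#' mean zero and unit variance for any `p >= 1`, so `(1/sqrt(d)) R` yields a
#' Johnson-Lindenstrauss style embedding; large `p` makes `R` very sparse
#' (expected nonzero fraction `1/p`). The default `p = sqrt(D)` follows the
#' standard very-sparse-projection recommendation.
#'
#' @param D source dimension (number of gene features).
#' @param d target dimension, `1 <= d < D`.
#' @param p sparsity parameter, `>= 1`; default `sqrt(D)`. `p = 1` gives a
#'   dense Rademacher (+/-1) matrix.
#' @param seed integer seed; the matrix is a deterministic function of
#'   `(D, d, p, seed)`.
#' @return an `rp_matrix`: list with the sparse matrix `R` (a
#'   [Matrix::sparseMatrix()]) and the generating parameters.
#' @examples
#' R <- rp_matrix(D = 500, d = 20, seed = 1)
#' mean(R$R != 0)  # about 1/sqrt(500)
#' @export
rp_matrix <- function(D, d, p = sqrt(D), seed = 1L) {
  if (!(length(D) == 1L && length(d) == 1L && D >= 2 && d >= 1 && d < D))
    stop("need 1 <= d < D", call. = FALSE)
  if (p < 1) stop("sparsity parameter p must be >= 1", call. = FALSE)
  D <- as.integer(D); d <- as.integer(d)
  n_cells <- as.numeric(d) * as.numeric(D)
  if (n_cells > .Machine$integer.max)
    stop("d * D too large for dense index sampling", call. = FALSE)
  R <- with_seed(seed, {
    k <- stats::rbinom(1L, as.integer(n_cells), 1 / p)
    if (k > 0L) {
      pos <- sample.int(as.integer(n_cells), k)
      i <- (pos - 1L) %% d + 1L
      j <- (pos - 1L) %/% d + 1L
      x <- sample(c(-1, 1), k, replace = TRUE) * sqrt(p)
      Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(d, D))
    } else {
      Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                           dims = c(d, D))
    }
  })
  structure(list(R = R, d = d, D = D, p = p, seed = as.integer(seed)),
            class = "rp_matrix")
}

#' @export
print.rp_matrix <- function(x, ...) {
  cat(sprintf(
    "rp_matrix: %d x %d, p = %.4g (nonzero fraction %.4g, expected %.4g), seed %d\n",
    x$d, x$D, x$p, Matrix::nnzero(x$R) / (as.numeric(x$d) * x$D), 1 / x$p,
    x$seed))
  invisible(x)
}

#' Project expression data to a low-dimensional subspace
#'
#' Computes `A = (1/sqrt(d)) R T` where `T` is the `D` x `N` (gene x sample)
#' data matrix. The `1/sqrt(d)` scaling makes squared distances between
#' projected samples unbiased estimates of the original squared distances.
#'
#' @param R an [rp_matrix()].
#' @param x a `D` x `N` [expression_matrix()] (typically log2TPM) or plain
#'   numeric matrix with genes in rows.
#' @return a `projected_data` object: list with `values` (`d` x `N` dense
#'   matrix, columns named by sample), `rp` (the generating parameters of
#'   `R`), and `sample_ids`.
#' @export
project <- function(R, x) {
  stopifnot(inherits(R, "rp_matrix"))
  v <- if (inherits(x, "expression_matrix")) unclass(x) else as.matrix(x)
  if (nrow(v) != R$D)
    stop(sprintf("dimension mismatch: projection expects %d genes, data has %d",
                 R$D, nrow(v)), call. = FALSE)
  A <- as.matrix(R$R %*% v) / sqrt(R$d)
  dimnames(A) <- list(NULL, colnames(v))
  structure(list(values = A,
                 rp = R[c("d", "D", "p", "seed")],
                 sample_ids = colnames(v)),
            class = "projected_data")
}

#' @export
print.projected_data <- function(x, ...) {
  cat(sprintf("projected_data: %d dims x %d samples (d=%d, D=%d, p=%.4g, seed=%d)\n",
              nrow(x$values), ncol(x$values), x$rp$d, x$rp$D, x$rp$p, x$rp$seed))
  invisible(x)
}

#' Distance preservation after projection
#'
#' Pearson correlation between the `N(N-1)/2` pairwise Euclidean
#' sample-to-sample distances in the original space and in the projected
#' space — the standard diagnostic for how faithfully a dimension-reduction
#' step preserves cohort geometry.
#'
#' @param x original data: `D` x `N` [expression_matrix()] or matrix,
#'   samples in columns.
#' @param a projected data: a `projected_data` object, or a matrix with
#'   samples in columns.
#' @return the correlation, in `[-1, 1]`.
#' @export
distance_pcc <- function(x, a) {
  xv <- if (inherits(x, "expression_matrix")) unclass(x) else as.matrix(x)
  av <- if (inherits(a, "projected_data")) a$values else as.matrix(a)
  if (ncol(xv) != ncol(av))
    stop("original and projected data must share the sample set", call. = FALSE)
  if (ncol(xv) < 3L) stop("need at least 3 samples", call. = FALSE)
  d0 <- as.vector(stats::dist(t(xv)))
  d1 <- as.vector(stats::dist(t(av)))
  if (stats::sd(d0) == 0 || stats::sd(d1) == 0)
    stop("zero-variance distance vector", call. = FALSE)
  stats::cor(d0, d1)
}

#' Distance-preservation sweep over target dimensions
#'
#' For each target dimension, projects the data with several independent
#' seeds and summarizes the distance-preservation correlation
#' ([distance_pcc()]). A variance-maximizing linear projection (PCA via
#' [stats::prcomp()]) is available as a comparison adapter.
#'
#' @param x `D` x `N` [expression_matrix()] or matrix, samples in columns.
#' @param dims integer vector of target dimensions; duplicates are collapsed
#'   and the sweep runs in increasing order.
#' @param p sparsity parameter; default `sqrt(D)`.
#' @param seeds integer vector of projection seeds (ignored by the
#'   deterministic PCA adapter, which contributes a single run).
#' @param method `"rp"` (sparse random projection) or `"pca"`.
#' @return data frame with one row per dimension: `dim`, `method`,
#'   `mean_pcc`, `sd_pcc`, `n_runs`.
#' @export
dimension_sweep <- function(x, dims, p = NULL, seeds = 1:5,
                            method = c("rp", "pca")) {
  method <- match.arg(method)
  if (!length(dims)) stop("'dims' must be nonempty", call. = FALSE)
  dims <- sort(unique(as.integer(dims)))
  xv <- if (inherits(x, "expression_matrix")) unclass(x) else as.matrix(x)
  D <- nrow(xv)
  p <- p %||% sqrt(D)
  rows <- lapply(dims, function(d) {
    pcc <- if (method == "rp") {
      vapply(seeds, function(s) distance_pcc(xv, project(rp_matrix(D, d, p, s), xv)),
             numeric(1))
    } else {
      dmax <- min(d, ncol(xv) - 1L, D)
      pc <- stats::prcomp(t(xv), center = TRUE, scale. = FALSE, rank. = dmax)
      distance_pcc(xv, t(pc$x))
    }
    data.frame(dim = d, method = method, mean_pcc = mean(pcc),
               sd_pcc = if (length(pcc) > 1L) stats::sd(pcc) else NA_real_,
               n_runs = length(pcc))
  })
  do.call(rbind, rows)
}
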