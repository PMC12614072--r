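#' One-hot encode predicted labels
#'
#' @param labels label vector (character or factor), each a member of
#'   `class_order`.
#' @param class_order column order of the encoding.
#' @return `N` x `C` 0/1 matrix with exactly one 1 per row.
#' @export
one_hot <- function(labels, class_order) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), class_order)
  if (length(bad))
    stop("unknown label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  m <- matrix(0L, length(labels), length(class_order),
              dimnames = list(names(labels), class_order))
  m[cbind(seq_along(labels), match(labels, class_order))] <- 1L
  m
}

#' Z-score matrix columns
#'
#' Centers each column to mean 0 and scales it to standard deviation 1
#' (sample sd, divide-by-`N-1`); zero-variance columns are mapped to
#' all-zeros rather than dividing by zero.
#'
#' @param m numeric matrix with at least 2 rows.
#' @return matrix of the same shape.
#' @export
zscore_columns <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop("need at least 2 rows to z-score", call. = FALSE)
  mu <- colMeans(m)
  s <- apply(m, 2L, stats::sd)
  out <- sweep(m, 2L, mu, "-")
  nz <- s > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2L, s[nz], "/")
  out[, !nz] <- 0
  out
}

#' Prediction-informed visualization matrix
#'
#' Concatenates a z-scored projected-feature block with a z-scored one-hot
#' prediction block: `V = [ w * Z(features) | Z(one_hot) ]`, samples in
#' rows. The weight ratio `w` balances the two blocks: `w > 1` emphasizes
#' the reduced feature space, `0 < w < 1` emphasizes the predicted subtype
#' information.
#'
#' @param features a `projected_data` object (from [project()]), or an
#'   `N` x `d` matrix with samples in rows.
#' @param predictions an `N` x `C` one-hot matrix ([one_hot()]), or a label
#'   vector together with `class_order`.
#' @param w positive weight ratio of the feature block over the prediction
#'   block; default 1.
#' @param class_order needed when `predictions` is a label vector.
#' @return a `vis_matrix`: `N` x `(d + C)` matrix with attributes
#'   `feature_cols`, `class_cols`, `w`, `zscore` (the sd convention).
#' @export
build_vis_matrix <- function(features, predictions, w = 1.0,
                             class_order = NULL) {
  if (!(is.numeric(w) && length(w) == 1L && w > 0))
    stop("weight ratio w must be a positive scalar", call. = FALSE)
  Fm <- if (inherits(features, "projected_data")) t(features$values)
        else as.matrix(features)
  Y <- if (is.matrix(predictions)) predictions
       else one_hot(predictions, class_order %||% sort(unique(as.character(predictions))))
  if (nrow(Fm) != nrow(Y))
    stop("feature and prediction blocks disagree on the sample set",
         call. = FALSE)
  if (!is.null(rownames(Fm)) && !is.null(rownames(Y)) &&
      !identical(rownames(Fm), rownames(Y)))
    stop("sample ids of the two blocks do not match", call. = FALSE)
  V <- cbind(w * zscore_columns(Fm), zscore_columns(Y))
  rownames(V) <- rownames(Fm) %||% rownames(Y)
  structure(V, feature_cols = ncol(Fm), class_cols = ncol(Y), w = w,
            zscore = "sample sd (N-1)",
            class = c("vis_matrix", "matrix", "array"))
}

#' Embed a visualization matrix in two dimensions
#'
#' Reduces the rows of the visualization matrix to 2-D coordinates with a
#' pluggable backend: classical metric MDS (default; deterministic) or
#' nonmetric MDS ([MASS::isoMDS()], initialized from the metric solution).
#' The neighborhood parameter is recorded with the result for backends that
#' use one. Identical rows map to identical (MDS) coordinates, and a fixed
#' seed reproduces the embedding exactly.
#'
#' @param V a [build_vis_matrix()] result, or any numeric matrix with
#'   samples in rows (`N >= 5`).
#' @param seed integer seed recorded with (and, for stochastic backends,
#'   driving) the embedding.
#' @param method `"mds"` or `"nmds"`.
#' @param neighborhood neighborhood-size parameter; default
#'   `min(30, (N - 1) / 3)`.
#' @return `N` x 2 coordinate matrix with attributes `method`, `seed`,
#'   `neighborhood`.
#' @export
embed_2d <- function(V, seed = 1L, method = c("mds", "nmds"),
                     neighborhood = NULL) {
  method <- match.arg(method)
  V <- as.matrix(V)
  n <- nrow(V)
  if (n < 5L) stop("need at least 5 samples to embed", call. = FALSE)
  neighborhood <- neighborhood %||% min(30, (n - 1) / 3)
  d <- stats::dist(V)
  coords <- if (method == "mds") {
    stats::cmdscale(d, k = 2L)
  } else {
    # isoMDS rejects zero dissimilarities; nudge ties by a seeded epsilon
    dm <- as.matrix(d)
    eps <- 1e-8 * max(dm)
    if (any(d <= 0)) d <- stats::as.dist(dm + eps * (dm <= 0))
    init <- stats::cmdscale(d, k = 2L)
    with_seed(seed, MASS::isoMDS(d, y = init, k = 2L, trace = FALSE)$points)
  }
  if (ncol(coords) < 2L)  # degenerate geometry: pad a zero axis
    coords <- cbind(coords, 0)[, 1:2, drop = FALSE]
  dimnames(coords) <- list(rownames(V), c("x", "y"))
  structure(coords, method = method, seed = as.integer(seed),
            neighborhood = neighborhood)
}

#' Plot a 2-D embedding colored by subtype
#'
#' Scatter plot of embedding coordinates with one color per subtype and a
#' legend; when `out_path` is given the plot is written as a vector file
#' (`.svg` or `.pdf` by extension) with fixed renderer settings.
#'
#' @param coords `N` x 2 coordinate matrix (e.g. from [embed_2d()]).
#' @param labels subtype label per sample; must be nonempty.
#' @param out_path optional output file path.
#' @param palette optional vector of colors, one per subtype level.
#' @param main plot title.
#' @param cex point size.
#' @return the label-to-color map, invisibly.
#' @export
plot_embedding <- function(coords, labels, out_path = NULL, palette = NULL,
                           main = "Prediction-informed embedding", cex = 0.8) {
  coords <- as.matrix(coords)
  labels <- as.character(labels)
  if (length(labels) == 0L || nrow(coords) == 0L)
    stop("empty coordinates or labels", call. = FALSE)
  if (nrow(coords) != length(labels))
    stop("coords and labels are not aligned", call. = FALSE)
  lev <- sort(unique(labels))
  palette <- palette %||% grDevices::hcl.colors(max(length(lev), 2L), "Dark 3")[seq_along(lev)]
  if (length(palette) < length(lev))
    stop("palette has fewer colors than subtypes", call. = FALSE)
  colmap <- stats::setNames(palette[seq_along(lev)], lev)
  if (!is.null(out_path)) {
    if (grepl("\\.svg$", out_path, ignore.case = TRUE))
      grDevices::svg(out_path, width = 8, height = 6)
    else grDevices::pdf(out_path, width = 8, height = 6, useDingbats = FALSE)
    on.exit(grDevices::dev.off())
  }
  graphics::par(mar = c(4, 4, 3, 10), xpd = TRUE)
  graphics::plot(coords[, 1], coords[, 2], col = colmap[labels], pch = 19,
                 cex = cex, xlab = "dim 1", ylab = "dim 2", main = main)
  graphics::legend("topright", inset = c(-0.35, 0), legend = lev,
                   col = colmap, pch = 19, cex = 0.6, bty = "n")
  invisible(colmap)
}
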