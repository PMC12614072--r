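#' Expression matrix with a unit tag
#'
#' A thin wrapper around a numeric gene-by-sample matrix that records the
#' expression unit of its entries. All preprocessing steps
#' ([filter_genes()], [counts_to_tpm()], [fpkm_to_tpm()], [log_transform()])
#' operate on and return this class, so the unit travels with the values and
#' unit-inconsistent operations fail early.
#'
#' @param values numeric matrix, genes in rows (unique rownames = gene ids),
#'   samples in columns (unique colnames = sample ids); no negative entries.
#' @param unit one of `"counts"`, `"FPKM"`, `"TPM"`, `"log2TPM"`.
#' @return an `expression_matrix`: the matrix with a `unit` attribute.
#' @examples
#' m <- matrix(rpois(6, 10), 3, 2,
#'             dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' x <- expression_matrix(m, "counts")
#' expr_unit(x)
#' @export
expression_matrix <- function(values,
                              unit = c("counts", "FPKM", "TPM", "log2TPM")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  if (nrow(values) == 0L || ncol(values) == 0L)
    stop("expression matrix has zero genes or zero samples", call. = FALSE)
  if (anyNA(values))
    stop("expression matrix contains missing values", call. = FALSE)
  if (any(values < 0))
    stop("expression values must be non-negative", call. = FALSE)
  gid <- rownames(values); sid <- colnames(values)
  if (is.null(gid) || is.null(sid))
    stop("gene ids (rownames) and sample ids (colnames) are required",
         call. = FALSE)
  if (anyDuplicated(gid))
    stop("duplicate gene ids: ",
         paste(unique(gid[duplicated(gid)])[1:min(3, sum(duplicated(gid)))],
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(sid))
    stop("duplicate sample ids", call. = FALSE)
  structure(values, unit = unit, class = c("expression_matrix", "matrix", "array"))
}

#' @rdname expression_matrix
#' @param x an `expression_matrix`.
#' @export
expr_unit <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  attr(x, "unit")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples [%s]\n",
              nrow(x), ncol(x), attr(x, "unit")))
  k <- min(5L, nrow(x)); j <- min(5L, ncol(x))
  print(unclass(x)[seq_len(k), seq_len(j), drop = FALSE])
  if (nrow(x) > k || ncol(x) > j) cat("...\n")
  invisible(x)
}

#' @export
`[.expression_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out))
    out <- structure(out, unit = attr(x, "unit"),
                     class = c("expression_matrix", "matrix", "array"))
  out
}

#' Read a gene-by-sample expression table
#'
#' Reads a delimited text file (TSV or CSV, chosen from the file extension
#' or by sniffing the header line) with a header row of sample ids and gene
#' ids in the first column. A MatrixMarket triplet file (`.mtx`) is also
#' accepted, in which case `gene_ids` and `sample_ids` must name one-id-per-line
#' text files.
#'
#' @param path path to the expression table.
#' @param unit expression unit of the stored values (see
#'   [expression_matrix()]).
#' @param gene_ids,sample_ids only for `.mtx` input: paths to row/column id
#'   files.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, unit = c("counts", "FPKM", "TPM", "log2TPM"),
                            gene_ids = NULL, sample_ids = NULL) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) stop("empty expression file: ", path, call. = FALSE)
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    if (is.null(gene_ids) || is.null(sample_ids))
      stop("MatrixMarket input requires 'gene_ids' and 'sample_ids' files",
           call. = FALSE)
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readLines(gene_ids)
    colnames(m) <- readLines(sample_ids)
    return(expression_matrix(m, unit))
  }
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  first <- readLines(path, n = 1L)
  if (!grepl(sep, first, fixed = TRUE) && grepl(",", first, fixed = TRUE))
    sep <- ","
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                      row.names = NULL, stringsAsFactors = FALSE,
                      comment.char = "", quote = "\""),
    error = function(e) stop("malformed expression file: ", conditionMessage(e),
                             call. = FALSE))
  if (ncol(df) < 2L)
    stop("expression table needs a gene-id column plus at least one sample",
         call. = FALSE)
  gid <- as.character(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals))
    stop("non-numeric expression values in ", path, call. = FALSE)
  rownames(vals) <- gid
  expression_matrix(vals, unit)
}

#' Keep genes expressed in a minimum fraction of samples
#'
#' A gene is called expressed in a sample when its value exceeds `threshold`
#' (default 0). Genes expressed in at least `ceiling(min_fraction * N)` of
#' the `N` samples are retained, so "at least 75%" is literal; gene order
#' and the sample set are unchanged. The operation is idempotent.
#'
#' @param x an [expression_matrix()] of counts, FPKM or TPM.
#' @param min_fraction required fraction of samples, in (0, 1]; default 0.75.
#' @param threshold expression call cutoff; a gene counts as expressed when
#'   strictly above this value.
#' @return the filtered [expression_matrix()].
#' @export
filter_genes <- function(x, min_fraction = 0.75, threshold = 0) {
  stopifnot(inherits(x, "expression_matrix"))
  if (!is.numeric(min_fraction) || length(min_fraction) != 1L ||
      min_fraction <= 0 || min_fraction > 1)
    stop("'min_fraction' must lie in (0, 1]", call. = FALSE)
  need <- ceiling(min_fraction * ncol(x))
  keep <- rowSums(unclass(x) > threshold) >= need
  if (!any(keep))
    stop("all genes removed by the prevalence filter", call. = FALSE)
  x[keep, , drop = FALSE]
}

#' Convert raw counts to TPM
#'
#' Per sample, each gene's count is divided by its effective length in
#' kilobases and the resulting rates are rescaled to sum to one million, so
#' every non-empty sample column sums to 1e6. A sample with zero total
#' counts stays all-zero.
#'
#' @param x an [expression_matrix()] with unit `"counts"`.
#' @param lengths named numeric vector of effective gene lengths in base
#'   pairs (all positive), or a two-column data frame (gene_id, length_bp).
#'   Every gene in `x` must be present.
#' @return an [expression_matrix()] with unit `"TPM"`.
#' @export
counts_to_tpm <- function(x, lengths) {
  stopifnot(inherits(x, "expression_matrix"))
  if (expr_unit(x) != "counts")
    stop("counts_to_tpm() expects unit 'counts', got '", expr_unit(x), "'",
         call. = FALSE)
  if (is.data.frame(lengths)) {
    if (ncol(lengths) < 2L) stop("length table needs two columns", call. = FALSE)
    lengths <- stats::setNames(as.numeric(lengths[[2L]]),
                               as.character(lengths[[1L]]))
  }
  miss <- setdiff(rownames(x), names(lengths))
  if (length(miss))
    stop("missing gene lengths for: ",
         paste(utils::head(miss, 3L), collapse = ", "),
         if (length(miss) > 3L) ", ...", call. = FALSE)
  len_kb <- lengths[rownames(x)] / 1000
  if (any(!is.finite(len_kb)) || any(len_kb <= 0))
    stop("gene lengths must be positive", call. = FALSE)
  rate <- unclass(x) / len_kb
  tot <- colSums(rate)
  tot[tot == 0] <- 1  # all-zero sample stays all-zero
  tpm <- sweep(rate, 2L, tot, "/") * 1e6
  expression_matrix(tpm, "TPM")
}

#' Convert FPKM to TPM
#'
#' FPKM already accounts for gene length, so TPM is obtained by rescaling
#' each sample column to sum to one million. TPM input is a fixed point of
#' this map.
#'
#' @param x an [expression_matrix()] with unit `"FPKM"`.
#' @return an [expression_matrix()] with unit `"TPM"`.
#' @export
fpkm_to_tpm <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  if (expr_unit(x) != "FPKM")
    stop("fpkm_to_tpm() expects unit 'FPKM', got '", expr_unit(x), "'",
         call. = FALSE)
  v <- unclass(x)
  tot <- colSums(v)
  tot[tot == 0] <- 1
  expression_matrix(sweep(v, 2L, tot, "/") * 1e6, "TPM")
}

#' Log-transform TPM values
#'
#' Elementwise `log2(TPM + 1)`; zeros map to zero and ordering of entries is
#' preserved.
#'
#' @param x an [expression_matrix()] with unit `"TPM"`.
#' @return an [expression_matrix()] with unit `"log2TPM"`.
#' @export
log_transform <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  if (expr_unit(x) != "TPM")
    stop("log_transform() expects unit 'TPM', got '", expr_unit(x), "'",
         call. = FALSE)
  expression_matrix(log2(unclass(x) + 1), "log2TPM")
}

#' Bring any supported unit to log2(TPM + 1)
#'
#' Convenience pipeline used at prediction time: counts are converted to TPM
#' (which requires `lengths`), FPKM is renormalized to TPM, TPM is
#' log-transformed, and log2TPM input passes through unchanged.
#'
#' @inheritParams counts_to_tpm
#' @return an [expression_matrix()] with unit `"log2TPM"`.
#' @export
as_log2tpm <- function(x, lengths = NULL) {
  stopifnot(inherits(x, "expression_matrix"))
  switch(expr_unit(x),
    log2TPM = x,
    TPM = log_transform(x),
    FPKM = log_transform(fpkm_to_tpm(x)),
    counts = {
      if (is.null(lengths))
        stop("count input needs a gene-length table for TPM conversion",
             call. = FALSE)
      log_transform(counts_to_tpm(x, lengths))
    })
}

#' Align an expression matrix to a training gene list
#'
#' Prediction-time matrices are matched to the fitted model's gene list by
#' id. If fewer than `min_coverage` of the training genes are present the
#' call errors; with `fill_missing = TRUE` absent genes are zero-filled
#' instead (an explicit opt-in, because silent zero-fill perturbs
#' projections).
#'
#' @param x an [expression_matrix()].
#' @param gene_ids character vector: the training gene list, in order.
#' @param min_coverage minimum fraction of `gene_ids` that must be present.
#' @param fill_missing zero-fill genes absent from `x`?
#' @return an [expression_matrix()] whose rows are exactly `gene_ids`.
#' @export
align_genes <- function(x, gene_ids, min_coverage = 0.9, fill_missing = FALSE) {
  stopifnot(inherits(x, "expression_matrix"))
  present <- intersect(gene_ids, rownames(x))
  cov <- length(present) / length(gene_ids)
  if (cov < min_coverage)
    stop(sprintf("only %.1f%% of training genes present (need >= %.1f%%)",
                 100 * cov, 100 * min_coverage), call. = FALSE)
  if (length(present) < length(gene_ids) && !fill_missing)
    stop(length(gene_ids) - length(present),
         " training genes absent from input; rerun with fill_missing = TRUE ",
         "to zero-fill them", call. = FALSE)
  out <- matrix(0, nrow = length(gene_ids), ncol = ncol(x),
                dimnames = list(gene_ids, colnames(x)))
  out[present, ] <- unclass(x)[present, , drop = FALSE]
  expression_matrix(out, expr_unit(x))
}
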