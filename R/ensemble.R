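#' Fit an ensemble of random-projection linear SVM classifiers
#'
#' The core model of the package. Each of the `M` ensemble members draws an
#' independent very sparse projection matrix ([rp_matrix()], seed
#' `seed + m`), projects the log2(TPM+1) training data onto `d` dimensions,
#' and fits one-vs-rest linear support vector machines on the projected
#' features. Per-class margins are mapped to calibrated probabilities with a
#' Platt sigmoid (fitted deterministically on the training margins with
#' smoothed targets) and normalized to a per-member class distribution.
#' Prediction averages the members' probability vectors.
#'
#' Projections are data-independent, so a fitted model is a deterministic
#' function of the data, the hyperparameters, and `seed`.
#'
#' @param x training expression: a `D` x `N` [expression_matrix()] with unit
#'   `"log2TPM"` (other units are converted via [as_log2tpm()]; counts need
#'   `lengths`), or a plain `D` x `N` matrix assumed to be log2TPM.
#' @param y subtype labels, one per sample (character or factor). Every
#'   class needs at least 2 training samples.
#' @param d target projection dimension; default 1200.
#' @param M ensemble size (number of independent projections); default 30.
#' @param p sparsity parameter of the projection; default `sqrt(D)`.
#' @param cost soft-margin cost of the linear SVMs; default 1.
#' @param seed master seed; member `m` uses seed `seed + m`.
#' @param scale_features standardize projected features before the SVM fit?
#'   Default `FALSE`.
#' @param class_weights weight classes inversely to their frequency?
#'   Default `FALSE`.
#' @param lengths gene-length table, only needed when `x` is counts.
#' @return an object of class `rp_ensemble` with components `members` (per
#'   member: projection seed plus a `d` x `C` weight matrix, intercepts and
#'   sigmoid coefficients), `class_order`, `train_gene_ids`, and the
#'   hyperparameters.
#' @examples
#' sim <- sim_expression(synth_spec(n_genes = 300, class_sizes = c(20, 20),
#'                                  effect_size = 3, seed = 1))
#' xl <- as_log2tpm(sim$expression, sim$lengths)
#' fit <- rp_ensemble(xl, sim$labels, d = 40, M = 3, seed = 1)
#' fit
#' @seealso [predict.rp_ensemble()], [repeated_cv()], [save_model()]
#' @export
rp_ensemble <- function(x, y, d = 1200L, M = 30L, p = NULL, cost = 1,
                        seed = 1L, scale_features = FALSE,
                        class_weights = FALSE, lengths = NULL) {
  if (inherits(x, "expression_matrix")) x <- as_log2tpm(x, lengths)
  v <- if (inherits(x, "expression_matrix")) unclass(x) else as.matrix(x)
  if (is.null(rownames(v)))
    rownames(v) <- paste0("feat_", seq_len(nrow(v)))
  y <- as.character(y)
  if (length(y) != ncol(v))
    stop("length(y) must equal the number of samples (columns)", call. = FALSE)
  class_order <- sort(unique(y))
  if (length(class_order) < 2L) stop("need at least 2 classes", call. = FALSE)
  tab <- table(y)
  if (any(tab < 2L))
    stop("every class needs >= 2 training samples; too small: ",
         paste(names(tab)[tab < 2L], collapse = ", "), call. = FALSE)
  D <- nrow(v)
  if (d >= D) stop("projection dimension d must be < number of genes D",
                   call. = FALSE)
  p <- p %||% sqrt(D)
  M <- as.integer(M)
  if (M < 1L) stop("ensemble size M must be >= 1", call. = FALSE)
  wts <- if (class_weights)
    stats::setNames(as.numeric(sum(tab) / (length(tab) * tab)), names(tab))
  else NULL

  members <- vector("list", M)
  for (m in seq_len(M)) {
    s_m <- member_seed(seed, m)
    R <- rp_matrix(D, d, p, s_m)
    A <- t(project(R, v)$values)                      # N x d
    if (scale_features) A <- scale(A)
    members[[m]] <- c(list(seed = s_m),
                      fit_member(A, y, class_order, cost, wts))
  }
  structure(list(members = members, class_order = class_order,
                 train_gene_ids = rownames(v),
                 d = as.integer(d), M = M, p = p, D = D, cost = cost,
                 seed = as.integer(seed), scale_features = scale_features,
                 class_weights = class_weights,
                 n_train = ncol(v), call = match.call(),
                 version = "rp_ensemble/1"),
            class = "rp_ensemble")
}

# One ensemble member: one-vs-rest linear SVMs on projected features plus a
# deterministic Platt sigmoid per class. Returns the stacked linear form:
# margins F = A %*% W + b, probabilities plogis(a0 + a1 * F), renormalized.
fit_member <- function(A, y, class_order, cost, wts) {
  d <- ncol(A); C <- length(class_order)
  W <- matrix(0, d, C, dimnames = list(NULL, class_order))
  b <- numeric(C); a0 <- numeric(C); a1 <- numeric(C)
  if (!is.null(wts)) {
    # inverse-frequency weight on the positive class of each binary task
    w2 <- function(cl) c(neg = 1, pos = unname(wts[cl]))
  }
  for (ci in seq_len(C)) {
    cl <- class_order[ci]
    pos <- y == cl
    yc <- factor(ifelse(pos, "pos", "neg"), levels = c("neg", "pos"))
    fit <- e1071::svm(A, yc, kernel = "linear", cost = cost, scale = FALSE,
                      class.weights = if (!is.null(wts)) w2(cl) else NULL)
    w <- drop(t(fit$coefs) %*% fit$SV)
    bi <- -fit$rho
    f <- drop(A %*% w) + bi
    # libsvm's margin sign depends on label encounter order; orient so that
    # positive margin <-> positive class
    if (mean(f[pos]) < mean(f[!pos])) {
      w <- -w; bi <- -bi; f <- -f
    }
    W[, ci] <- w; b[ci] <- bi
    sig <- platt_sigmoid(f, pos)
    a0[ci] <- sig[1]; a1[ci] <- sig[2]
  }
  list(W = W, b = b, a0 = a0, a1 = a1)
}

# Platt scaling with smoothed targets t+ = (n+ + 1)/(n+ + 2), t- = 1/(n- + 2);
# the smoothing keeps the logistic fit finite even on separable margins.
# The slope is unconstrained, so margin orientation is absorbed here too.
platt_sigmoid <- function(f, pos) {
  n_pos <- sum(pos); n_neg <- sum(!pos)
  t <- ifelse(pos, (n_pos + 1) / (n_pos + 2), 1 / (n_neg + 2))
  fit <- tryCatch(
    stats::glm(t ~ f, family = stats::quasibinomial()),
    error = function(e) NULL)
  if (is.null(fit) || anyNA(stats::coef(fit))) {
    # degenerate margins (e.g. constant f): fall back to a unit-slope sigmoid
    return(c(-mean(f), 1))
  }
  unname(stats::coef(fit))
}

#' Predict subtypes with a fitted projection ensemble
#'
#' New samples are aligned to the training gene list ([align_genes()]),
#' converted to log2(TPM+1) if needed, projected with each member's
#' regenerated projection matrix, and scored. The ensemble score for class
#' `c` is the average of the members' calibrated probabilities, so each row
#' of the score matrix sums to 1; the predicted label is the argmax, with
#' ties broken toward the first class in `class_order`.
#'
#' @param object an [rp_ensemble()] fit.
#' @param newdata `D` x `N` [expression_matrix()] (any unit) or plain matrix
#'   assumed log2TPM.
#' @param type `"prob"` for the `N` x `C` ensemble score matrix (with the
#'   predicted labels and row-maximum confidences as attributes), `"class"`
#'   for the label factor, `"margin"` for the average of the raw
#'   (uncalibrated) one-vs-rest SVM margins.
#' @param members also return the per-member score array (`N` x `C` x `M`,
#'   attribute `"member_scores"`)? Default `FALSE`.
#' @param fill_missing,min_coverage passed to [align_genes()].
#' @param lengths gene lengths, needed only for count input.
#' @param ... unused.
#' @return see `type`.
#' @export
predict.rp_ensemble <- function(object, newdata,
                                type = c("prob", "class", "margin"),
                                members = FALSE, fill_missing = FALSE,
                                min_coverage = 0.9, lengths = NULL, ...) {
  type <- match.arg(type)
  if (inherits(newdata, "expression_matrix")) {
    newdata <- as_log2tpm(newdata, lengths)
    newdata <- align_genes(newdata, object$train_gene_ids,
                           min_coverage = min_coverage,
                           fill_missing = fill_missing)
    v <- unclass(newdata)
  } else {
    v <- as.matrix(newdata)
    if (nrow(v) != object$D)
      stop("matrix input must have the model's ", object$D, " genes in rows",
           call. = FALSE)
  }
  C <- length(object$class_order); N <- ncol(v)
  acc <- matrix(0, N, C, dimnames = list(colnames(v), object$class_order))
  marg <- matrix(0, N, C, dimnames = dimnames(acc))
  keep <- if (members) array(NA_real_, c(N, C, object$M)) else NULL
  for (m in seq_len(object$M)) {
    mem <- object$members[[m]]
    R <- rp_matrix(object$D, object$d, object$p, mem$seed)
    A <- t(project(R, v)$values)
    if (object$scale_features) A <- scale(A)
    Fm <- sweep(A %*% mem$W, 2L, mem$b, "+")
    Pm <- stats::plogis(sweep(sweep(Fm, 2L, mem$a1, "*"), 2L, mem$a0, "+"))
    Pm <- Pm / rowSums(Pm)
    acc <- acc + Pm
    marg <- marg + Fm
    if (members) keep[, , m] <- Pm
  }
  scores <- acc / object$M
  labs <- factor(object$class_order[max.col(scores, ties.method = "first")],
                 levels = object$class_order)
  names(labs) <- colnames(v)
  if (type == "class") {
    if (members) attr(labs, "member_scores") <- keep
    return(labs)
  }
  if (type == "margin") {
    out <- marg / object$M
    if (members) attr(out, "member_scores") <- keep
    return(out)
  }
  attr(scores, "labels") <- labs
  attr(scores, "confidence") <- apply(scores, 1L, max)
  if (members) attr(scores, "member_scores") <- keep
  scores
}

#' @export
print.rp_ensemble <- function(x, ...) {
  cat("Ensemble random-projection subtype classifier\n")
  cat(sprintf("  %d members | d = %d of D = %d genes | p = %.4g | cost = %g | seed = %d\n",
              x$M, x$d, x$D, x$p, x$cost, x$seed))
  cat(sprintf("  %d classes: %s\n", length(x$class_order),
              paste(utils::head(x$class_order, 6L), collapse = ", ")))
  if (length(x$class_order) > 6L) cat("    ...\n")
  cat(sprintf("  trained on %d samples\n", x$n_train))
  invisible(x)
}

#' @export
summary.rp_ensemble <- function(object, ...) {
  structure(list(model = object,
                 member_seeds = vapply(object$members, `[[`, integer(1), "seed"),
                 nonzero_expected = 1 / object$p),
            class = "summary.rp_ensemble")
}

#' @export
print.summary.rp_ensemble <- function(x, ...) {
  print(x$model)
  cat(sprintf("  member projection seeds: %s\n",
              paste(utils::head(x$member_seeds, 8L), collapse = ", ")))
  cat(sprintf("  expected projection nonzero fraction: %.4g\n",
              x$nonzero_expected))
  invisible(x)
}

#' Save / load a fitted ensemble model
#'
#' `save_model()` writes a single-file archive (serialized R object wrapped
#' with a format-version tag); `load_model()` validates the tag and returns
#' the model. The archive records the hyperparameters, all member projection
#' seeds, the class order, and the training gene list, and a loaded model
#' reproduces predictions bit-exactly.
#'
#' @param model an [rp_ensemble()] fit.
#' @param path file path (conventionally `.rbl`).
#' @return `load_model()` returns the `rp_ensemble` object; `save_model()`
#'   returns `path` invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "rp_ensemble"))
  saveRDS(list(format = "rp_ensemble/1", model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("corrupted or unreadable model archive: ",
                                           conditionMessage(e), call. = FALSE))
  if (!is.list(obj) || !identical(obj$format, "rp_ensemble/1") ||
      !inherits(obj$model, "rp_ensemble"))
    stop("not an rp_ensemble model archive (format mismatch)", call. = FALSE)
  obj$model
}
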