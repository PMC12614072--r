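# Stratified fold assignment: per class, shuffle the class's samples and
# deal them to folds in rotation, so per-fold class proportions are within
# one sample of the stratified target. Classes with fewer members than k
# simply occupy fewer folds (small-class policy); they are listed in a
# warning because their held-out estimates are fragile.
make_folds <- function(y, k, seed, warn_small = TRUE) {
  y <- as.character(y)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  fold <- integer(length(y))
  small <- character()
  with_seed(seed, {
    start <- 0L
    for (cl in sort(unique(y))) {
      idx <- which(y == cl)
      if (length(idx) < k) small <- c(small, cl)
      idx <- idx[sample.int(length(idx))]
      # rotate the starting fold per class so small classes spread over folds
      fold[idx] <- ((start + seq_along(idx) - 1L) %% k) + 1L
      start <- start + length(idx)
    }
  })
  if (warn_small && length(small))
    warning("class(es) with fewer members than k folds: ",
            paste(small, collapse = ", "), call. = FALSE)
  fold
}

#' Repeated stratified k-fold cross-validation
#'
#' Runs `repeats` rounds of stratified `k`-fold cross-validation of the
#' projection ensemble. Folds are re-randomized every repeat; within a
#' repeat the classifiers are refit per fold while the (data-independent)
#' projection seeds are shared across folds. Per repeat, predictions on the
#' held-out folds are pooled into one confusion matrix and aggregate
#' metrics.
#'
#' @param x `D` x `N` log2TPM [expression_matrix()] or matrix.
#' @param y labels, one per sample.
#' @param k number of folds (default 5).
#' @param repeats number of CV repeats (default 2; the full-cohort protocol
#'   uses 100).
#' @param d,M,p,cost,class_weights passed to [rp_ensemble()].
#' @param seed master seed; repeat `r` derives its fold and model seeds from
#'   it.
#' @param scheme optional [subtype_scheme()] for group metrics per repeat.
#' @param track_members also record each ensemble member's individual
#'   held-out accuracy (needed for ensemble-vs-individual comparisons)?
#' @return a `cv_result`: list with `metrics` (data frame, one row per
#'   repeat: accuracy, f1_weighted, f1_macro, mcc), `reports` (per-repeat
#'   [metrics_report()]s), `member_accuracy` (repeats x M matrix when
#'   tracked), and the settings.
#' @export
repeated_cv <- function(x, y, k = 5L, repeats = 2L, d = 1200L, M = 30L,
                        p = NULL, cost = 1, seed = 1L, scheme = NULL,
                        class_weights = FALSE, track_members = FALSE) {
  v <- if (inherits(x, "expression_matrix")) unclass(x) else as.matrix(x)
  y <- as.character(y)
  stopifnot(length(y) == ncol(v))
  class_order <- sort(unique(y))
  reports <- vector("list", repeats)
  mem_acc <- if (track_members) matrix(NA_real_, repeats, M) else NULL
  rows <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    fold <- make_folds(y, k, member_seed(seed, 7919L * r), warn_small = r == 1L)
    pred <- character(length(y))
    mem_ok <- if (track_members) matrix(NA, length(y), M) else NULL
    for (f in sort(unique(fold))) {
      te <- fold == f
      fit <- rp_ensemble(v[, !te, drop = FALSE], y[!te], d = d, M = M, p = p,
                         cost = cost, seed = member_seed(seed, r),
                         class_weights = class_weights)
      sc <- predict(fit, v[, te, drop = FALSE], type = "prob",
                    members = track_members)
      pred[te] <- as.character(attr(sc, "labels"))
      if (track_members) {
        ms <- attr(sc, "member_scores")
        for (m in seq_len(M)) {
          lab_m <- fit$class_order[max.col(ms[, , m, drop = FALSE][, , 1L],
                                           ties.method = "first")]
          mem_ok[te, m] <- lab_m == y[te]
        }
      }
    }
    reports[[r]] <- metrics_report(y, pred, class_order, scheme)
    if (track_members) mem_acc[r, ] <- colMeans(mem_ok)
    a <- reports[[r]]$aggregate
    rows[[r]] <- data.frame(repeat_id = r, accuracy = a$accuracy,
                            f1_weighted = a$f1_weighted, f1_macro = a$f1_macro,
                            mcc = a$mcc)
  }
  metrics <- do.call(rbind, rows)
  structure(list(metrics = metrics, reports = reports,
                 member_accuracy = mem_acc,
                 k = k, repeats = repeats, d = d, M = M, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %d x %d-fold stratified CV (d = %d, M = %d)\n",
              x$repeats, x$k, x$d, x$M))
  m <- x$metrics
  cat(sprintf("  accuracy %.4f (sd %.4f) | F1w %.4f | MCC %.4f\n",
              mean(m$accuracy), stats::sd(m$accuracy),
              mean(m$f1_weighted), mean(m$mcc)))
  invisible(x)
}

#' Stratified hold-out split
#'
#' Randomly assigns `round(fraction * N)` samples to the test set, allocated
#' across classes proportionally to class size by largest-remainder
#' rounding; every class keeps at least one training sample.
#'
#' @param y labels, one per sample.
#' @param fraction test fraction in (0, 1); default 0.30.
#' @param seed integer seed; the split is reproducible.
#' @return list with integer index vectors `train` and `test`.
#' @export
holdout_split <- function(y, fraction = 0.30, seed = 1L) {
  y <- as.character(y)
  if (!(fraction > 0 && fraction < 1))
    stop("fraction must lie in (0, 1)", call. = FALSE)
  n <- length(y)
  classes <- sort(unique(y))
  n_c <- vapply(classes, function(cl) sum(y == cl), integer(1))
  target <- fraction * n_c
  base <- floor(target)
  total <- round(fraction * n)
  rem <- order(target - base, decreasing = TRUE)
  take <- base
  extra <- total - sum(base)
  i <- 1L
  while (extra > 0L && i <= length(rem)) {
    take[rem[i]] <- take[rem[i]] + 1L
    extra <- extra - 1L; i <- i + 1L
  }
  take <- pmin(take, n_c - 1L)  # never empty a class's training side
  test <- integer()
  with_seed(seed, {
    for (ci in seq_along(classes)) {
      idx <- which(y == classes[ci])
      if (take[ci] > 0L)
        test <- c(test, idx[sample.int(length(idx), take[ci])])
    }
  })
  test <- sort(test)
  list(train = setdiff(seq_len(n), test), test = test)
}
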