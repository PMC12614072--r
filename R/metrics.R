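#' Confusion matrix
#'
#' Entry `(i, j)` counts samples whose true class is `class_order[i]` and
#' predicted class is `class_order[j]`. Row sums therefore equal the true
#' class counts and all entries sum to the number of samples.
#'
#' @param y_true,y_pred equal-length label vectors.
#' @param class_order class labels in a fixed order; default the sorted
#'   union of observed labels. Labels outside `class_order` are an error.
#' @return a `C` x `C` integer matrix with dimnames `true` x `predicted`.
#' @export
confusion_matrix <- function(y_true, y_pred, class_order = NULL) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred))
    stop("label vectors differ in length", call. = FALSE)
  class_order <- class_order %||% sort(unique(c(y_true, y_pred)))
  bad <- setdiff(unique(c(y_true, y_pred)), class_order)
  if (length(bad))
    stop("label(s) outside class_order: ", paste(bad, collapse = ", "),
         call. = FALSE)
  tt <- table(factor(y_true, levels = class_order),
              factor(y_pred, levels = class_order))
  m <- matrix(as.integer(tt), nrow = length(class_order),
              dimnames = list(true = class_order, predicted = class_order))
  m
}

#' Binary classification metrics
#'
#' Accuracy, F1 and the Matthews correlation coefficient from one-vs-rest
#' counts:
#' `Acc = (TP + TN) / (TP + FP + FN + TN)`,
#' `F1 = 2 TP / (2 TP + FP + FN)`,
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' When any factor of the MCC radicand is zero the MCC is defined as 0 (the
#' usual convention); F1 is 0 when its denominator vanishes. Inputs may be
#' vectors (recycled elementwise).
#'
#' @param tp,fp,tn,fn non-negative counts; `tp+fp+tn+fn` must be positive.
#' @return data frame with columns `accuracy`, `f1`, `mcc`.
#' @export
binary_metrics <- function(tp, fp, tn, fn) {
  n <- tp + fp + tn + fn
  if (any(c(tp, fp, tn, fn) < 0) || any(n == 0))
    stop("counts must be non-negative and not all zero", call. = FALSE)
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  tn <- as.numeric(tn); fn <- as.numeric(fn)
  acc <- (tp + tn) / n
  f1_den <- 2 * tp + fp + fn
  f1 <- ifelse(f1_den == 0, 0, 2 * tp / f1_den)
  rad <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- ifelse(rad == 0, 0, (tp * tn - fp * fn) / sqrt(rad))
  data.frame(accuracy = acc, f1 = f1, mcc = mcc)
}

#' Aggregate multiclass metrics from a confusion matrix
#'
#' Overall accuracy is `trace / N`. F1 is aggregated over the per-class
#' one-vs-rest F1 scores both support-weighted (default headline, robust
#' under class imbalance) and macro (unweighted mean over classes with
#' nonzero support). The multiclass MCC is Gorodkin's generalization
#' `(N*trace - sum(t_k p_k)) / sqrt((N^2 - sum(p_k^2)) (N^2 - sum(t_k^2)))`
#' with `t_k`/`p_k` the true/predicted class totals; the mean of the
#' per-class one-vs-rest binary MCCs is reported alongside. For two classes
#' the Gorodkin form reduces to the binary MCC.
#'
#' @param confusion square confusion matrix (rows = true), e.g. from
#'   [confusion_matrix()].
#' @return list with `accuracy`, `f1_weighted`, `f1_macro`, `mcc`
#'   (Gorodkin), `mcc_ovr_mean`, and the `per_class` data frame (TP, FP, TN,
#'   FN, accuracy, F1, MCC, recall and support per class).
#' @export
multiclass_metrics <- function(confusion) {
  cm <- as.matrix(confusion)
  if (nrow(cm) != ncol(cm) || nrow(cm) == 0L)
    stop("confusion matrix must be square and nonempty", call. = FALSE)
  n <- sum(cm)
  if (n == 0) stop("empty confusion matrix", call. = FALSE)
  tp <- diag(cm)
  t_k <- rowSums(cm)            # true class totals
  p_k <- colSums(cm)            # predicted class totals
  fn <- t_k - tp; fp <- p_k - tp; tn <- n - tp - fp - fn
  pc <- binary_metrics(tp, fp, tn, fn)
  pc <- cbind(data.frame(class = rownames(cm) %||% as.character(seq_len(nrow(cm))),
                         tp = as.integer(tp), fp = as.integer(fp),
                         tn = as.integer(tn), fn = as.integer(fn)),
              pc,
              data.frame(recall = ifelse(t_k == 0, NA_real_, tp / t_k),
                         support = as.integer(t_k)))
  rownames(pc) <- NULL
  supported <- t_k > 0
  num <- n * sum(tp) - sum(as.numeric(t_k) * p_k)
  den <- sqrt(n^2 - sum(as.numeric(p_k)^2)) * sqrt(n^2 - sum(as.numeric(t_k)^2))
  list(accuracy = sum(tp) / n,
       f1_weighted = sum(pc$f1 * t_k) / n,
       f1_macro = mean(pc$f1[supported]),
       mcc = if (den == 0) 0 else num / den,
       mcc_ovr_mean = mean(pc$mcc[supported]),
       per_class = pc)
}

#' Full evaluation report
#'
#' Bundles the confusion matrix, per-class one-vs-rest counts and metrics,
#' aggregate metrics, and (when a [subtype_scheme()] with groups is given)
#' subtype-group rollups into a single printable object.
#'
#' @inheritParams confusion_matrix
#' @param scheme optional [subtype_scheme()] for group-level metrics.
#' @return a `metrics_report`: list with `confusion`, `per_class`,
#'   `aggregate` and optionally `group_metrics`.
#' @export
metrics_report <- function(y_true, y_pred, class_order = NULL, scheme = NULL) {
  cm <- confusion_matrix(y_true, y_pred, class_order)
  agg <- multiclass_metrics(cm)
  out <- list(confusion = cm, per_class = agg$per_class,
              aggregate = agg[c("accuracy", "f1_weighted", "f1_macro",
                                "mcc", "mcc_ovr_mean")],
              n = sum(cm))
  if (!is.null(scheme) && length(scheme$group_map))
    out$group_metrics <- group_metrics(cm, scheme)
  structure(out, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cat(sprintf("metrics_report: %d samples, %d classes\n", x$n, nrow(x$confusion)))
  a <- x$aggregate
  cat(sprintf("  accuracy %.4f | F1 (weighted) %.4f | F1 (macro) %.4f | MCC %.4f\n",
              a$accuracy, a$f1_weighted, a$f1_macro, a$mcc))
  if (!is.null(x$group_metrics)) {
    cat("  group metrics:\n")
    print(x$group_metrics, digits = digits)
  }
  invisible(x)
}

#' Subtype-group metric rollups
#'
#' For each subtype group, the rows of the confusion matrix belonging to the
#' group's classes are kept with their within-group columns resolved
#' per-class, and predictions landing outside the group are collapsed into a
#' single "outside" column; aggregate metrics are computed on that
#' sub-confusion (classes with zero support are excluded from macro
#' averaging). The group accuracy is therefore the fraction of the group's
#' samples predicted as their exact subtype.
#'
#' @param confusion confusion matrix (or a `metrics_report`).
#' @param scheme a [subtype_scheme()] whose `group_map` covers every class
#'   present in the confusion matrix.
#' @return data frame: one row per group with `group`, `n`, `accuracy`,
#'   `f1_weighted`, `mcc`.
#' @export
group_metrics <- function(confusion, scheme) {
  if (inherits(confusion, "metrics_report")) confusion <- confusion$confusion
  cm <- as.matrix(confusion)
  classes <- rownames(cm)
  miss <- setdiff(classes, names(scheme$group_map))
  if (length(miss))
    stop("class(es) without a group: ", paste(miss, collapse = ", "),
         call. = FALSE)
  groups <- unique(scheme$group_map[classes])
  rows <- lapply(groups, function(g) {
    gcl <- intersect(classes, names(scheme$group_map)[scheme$group_map == g])
    sub <- cm[gcl, , drop = FALSE]
    within <- sub[, gcl, drop = FALSE]
    outside <- rowSums(sub) - rowSums(within)
    sq <- rbind(cbind(within, outside = outside),
                outside = rep(0L, length(gcl) + 1L))
    agg <- multiclass_metrics(sq)
    data.frame(group = g, n = sum(sub), accuracy = agg$accuracy,
               f1_weighted = agg$f1_weighted, mcc = agg$mcc)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
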