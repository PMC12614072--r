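# Independent metric oracles: direct transcriptions of the defining
# formulas, structured differently from the package implementations.

oracle_binary <- function(tp, fp, tn, fn) {
  acc <- (tp + tn) / (tp + fp + fn + tn)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  c(acc, f1, mcc)
}

# Multiclass MCC as the correlation of centered one-hot truth/prediction
# matrices over the expanded per-sample label vectors -- an independent
# route to the Gorodkin confusion-matrix formula.
oracle_mcc <- function(cm) {
  yt <- rep(seq_len(nrow(cm)), times = rowSums(cm))
  yp <- unlist(lapply(seq_len(nrow(cm)), function(i)
    rep(seq_len(ncol(cm)), times = cm[i, ])))
  C <- nrow(cm)
  X <- matrix(0, length(yt), C); X[cbind(seq_along(yt), yt)] <- 1
  Y <- matrix(0, length(yp), C); Y[cbind(seq_along(yp), yp)] <- 1
  cx <- scale(X, scale = FALSE); cy <- scale(Y, scale = FALSE)
  den <- sqrt(sum(cx * cx)) * sqrt(sum(cy * cy))
  if (den == 0) 0 else sum(cx * cy) / den
}

oracle_weighted_f1 <- function(cm) {
  f1s <- vapply(seq_len(nrow(cm)), function(k) {
    tp <- cm[k, k]; fp <- sum(cm[, k]) - tp; fn <- sum(cm[k, ]) - tp
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  sum(f1s * rowSums(cm)) / sum(cm)
}
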