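test_that("confusion matrix counts true-by-predicted pairs", {
  cls <- c("A", "B", "C")
  y <- c("A", "A", "B", "C")
  cm <- confusion_matrix(y, y, cls)
  expect_equal(diag(cm), c(A = 2L, B = 1L, C = 1L))
  expect_equal(sum(cm) - sum(diag(cm)), 0L)
  cm2 <- confusion_matrix("A", "B", cls)
  expect_equal(cm2["A", "B"], 1L)
  expect_equal(sum(cm2), 1L)
  # conservation: row sums are the true class counts
  set.seed(5)
  yt <- sample(cls, 60, replace = TRUE)
  yp <- sample(cls, 60, replace = TRUE)
  cmr <- confusion_matrix(yt, yp, cls)
  expect_equal(rowSums(cmr), table(factor(yt, cls))[cls], ignore_attr = TRUE)
  expect_equal(sum(cmr), 60L)
  expect_error(confusion_matrix(c("A", "Z"), c("A", "A"), cls), "outside")
})

test_that("binary metrics match their defining formulas", {
  m <- binary_metrics(50, 5, 40, 5)
  expect_equal(m$accuracy, 0.9)
  expect_equal(m$f1, 100 / 110)
  expect_equal(m$mcc, 1975 / 2475)
  # perfect classifier
  mp <- binary_metrics(10, 0, 7, 0)
  expect_equal(unlist(mp), c(accuracy = 1, f1 = 1, mcc = 1))
  # fully wrong: MCC hits the -1 limit through the direct formula
  mw <- binary_metrics(0, 6, 0, 4)
  expect_equal(unlist(mw), c(accuracy = 0, f1 = 0, mcc = -1))
  # zero-denominator guard
  expect_equal(binary_metrics(0, 0, 5, 0)$mcc, 0)
  expect_error(binary_metrics(0, 0, 0, 0), "not all zero")
})

test_that("binary metrics agree with the oracle on a count grid", {
  grid <- expand.grid(tp = 0:6, fp = 0:6, tn = 0:6, fn = 0:6)
  grid <- grid[rowSums(grid) > 0, ]
  got <- binary_metrics(grid$tp, grid$fp, grid$tn, grid$fn)
  want <- t(mapply(oracle_binary, grid$tp, grid$fp, grid$tn, grid$fn))
  expect_equal(got$accuracy, want[, 1], tolerance = 1e-12)
  expect_equal(got$f1, want[, 2], tolerance = 1e-12)
  expect_equal(got$mcc, want[, 3], tolerance = 1e-12)
})

test_that("F1 ignores true negatives and MCC flips sign under inversion", {
  a <- binary_metrics(12, 3, 5, 4)
  b <- binary_metrics(12, 3, 500, 4)
  expect_equal(a$f1, b$f1)
  # swapping predictions (tp<->fn, tn<->fp) negates MCC
  f <- binary_metrics(12, 3, 5, 4)
  r <- binary_metrics(4, 5, 3, 12)
  expect_equal(r$mcc, -f$mcc)
})

test_that("multiclass aggregates match independent oracles", {
  # perfect prediction
  d <- diag(c(5L, 3L, 2L)); dimnames(d) <- list(letters[1:3], letters[1:3])
  agg <- multiclass_metrics(d)
  expect_equal(agg$accuracy, 1); expect_equal(agg$f1_weighted, 1)
  expect_equal(agg$mcc, 1)
  # 2-class reduction: Gorodkin equals binary MCC
  cm2 <- matrix(c(30L, 4L, 6L, 10L), 2, 2, byrow = TRUE)
  expect_equal(multiclass_metrics(cm2)$mcc,
               binary_metrics(30, 6, 10, 4)$mcc, tolerance = 1e-12)
  # random confusion matrices vs the one-hot-correlation oracle
  set.seed(99)
  for (i in 1:25) {
    cm <- matrix(rpois(16, 4), 4, 4)
    if (sum(cm) == 0) cm[1, 1] <- 1
    agg <- multiclass_metrics(cm)
    expect_equal(agg$mcc, oracle_mcc(cm), tolerance = 1e-12)
    expect_equal(agg$f1_weighted, oracle_weighted_f1(cm), tolerance = 1e-12)
    expect_equal(agg$accuracy, sum(diag(cm)) / sum(cm), tolerance = 1e-12)
  }
})

test_that("aggregate accuracy equals mean per-sample correctness", {
  set.seed(3)
  cls <- letters[1:5]
  yt <- sample(cls, 200, replace = TRUE)
  yp <- ifelse(runif(200) < 0.7, yt, sample(cls, 200, replace = TRUE))
  rep <- metrics_report(yt, yp, cls)
  expect_equal(rep$aggregate$accuracy, mean(yt == yp), tolerance = 1e-12)
  expect_equal(sum(rep$confusion), 200L)
  # per-class counts: TP+FP+TN+FN = N for every class
  expect_true(all(with(rep$per_class, tp + fp + tn + fn) == 200L))
})

test_that("group metrics roll subtypes up into their groups", {
  sc <- ball_scheme()
  cls <- sc$labels
  # all-correct predictions: every group scores 1
  yt <- rep(cls, each = 3)
  rep1 <- metrics_report(yt, yt, cls, scheme = sc)
  expect_true(all(rep1$group_metrics$accuracy == 1))
  expect_equal(rep1$group_metrics$mcc, rep(1, 4), tolerance = 1e-12)
  expect_setequal(rep1$group_metrics$group,
                  c("Fusion Gene", "TF Alteration", "Ploidy", "Rare Subtype"))
  # a within-group confusion hurts accuracy but stays in the group's rows
  yp <- yt
  yp[yt == "Ph"][1] <- "Ph-like"          # Fusion Gene internal error
  rep2 <- metrics_report(yt, yp, cls, scheme = sc)
  gm <- rep2$group_metrics
  fus <- gm[gm$group == "Fusion Gene", ]
  expect_lt(fus$accuracy, 1)
  expect_true(all(gm$accuracy[gm$group != "Fusion Gene"] == 1))
  # class without a group is an error
  sc2 <- sc; sc2$group_map <- sc$group_map[-1]
  expect_error(group_metrics(rep2$confusion, sc2), "without a group")
})

test_that("stratified hold-out split meets its size and safety contracts", {
  y <- rep(c("A", "B", "C"), c(60, 30, 10))
  sp <- holdout_split(y, 0.3, seed = 1)
  expect_length(sp$test, 30L)
  expect_setequal(c(sp$train, sp$test), seq_along(y))
  expect_length(intersect(sp$train, sp$test), 0L)
  # stratified: per-class test counts near fraction * n_c
  expect_equal(sum(y[sp$test] == "A"), 18L)
  expect_equal(sum(y[sp$test] == "C"), 3L)
  # reproducibility
  expect_identical(holdout_split(y, 0.3, seed = 1), sp)
  # a tiny class never empties its training side
  y2 <- rep(c("A", "B"), c(97, 3))
  sp2 <- holdout_split(y2, 0.3, seed = 2)
  expect_gte(sum(y2[sp2$train] == "B"), 1L)
  expect_error(holdout_split(y, 1.2), "fraction")
})

test_that("repeated CV stratifies, partitions, and is reproducible", {
  dat <- make_classes(D = 120, sizes = c(30, 20, 10), effect = 4, seed = 40)
  cv1 <- repeated_cv(dat$x, dat$y, k = 5, repeats = 2, d = 30, M = 2, seed = 1)
  cv2 <- repeated_cv(dat$x, dat$y, k = 5, repeats = 2, d = 30, M = 2, seed = 1)
  expect_identical(cv1$metrics, cv2$metrics)
  expect_equal(nrow(cv1$metrics), 2L)
  # strong signal: high accuracy
  expect_gte(mean(cv1$metrics$accuracy), 0.95)
  # fold construction: partition + stratification within one sample
  fold <- rpsubtype:::make_folds(dat$y, 5, seed = 3, warn_small = FALSE)
  expect_setequal(unique(fold), 1:5)
  expect_length(fold, length(dat$y))
  for (cl in unique(dat$y)) {
    per_fold <- table(factor(fold[dat$y == cl], levels = 1:5))
    expect_lte(diff(range(per_fold)), 1)
  }
  expect_error(rpsubtype:::make_folds(dat$y, 1, seed = 1), "k must be")
  # small-class policy warns
  ysmall <- c(rep("A", 20), rep("B", 3))
  expect_warning(rpsubtype:::make_folds(ysmall, 5, seed = 1), "fewer members")
})
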