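test_that("z-score standardization uses training statistics only", {
  X <- cbind(a = c(1, 2, 3), b = c(4, 4, 4))
  tb <- feature_table(c("x", "y", "z"), X, c(0L, 1L, 0L))
  st <- zscore_fit(tb)
  z <- zscore_apply(st, tb)
  expect_equal(unname(z$X[, 1]), c(-1, 0, 1) / sqrt(2 / 3))  # population sd
  expect_equal(unname(z$X[, 2]), c(0, 0, 0))                 # constant -> 0
  expect_equal(unname(st$sds[2]), 1)
  expect_lt(max(abs(colMeans(z$X))), 1e-12)

  other <- feature_table("w", matrix(c(10, 20), 1, 2,
                                     dimnames = list(NULL, c("a", "b"))), 1L)
  z2 <- zscore_apply(st, other)          # stored state, unchanged
  expect_equal(unname(z2$X[1, 1]), (10 - 2) / sqrt(2 / 3))
  bad <- feature_table("w", matrix(1, 1, 2,
                                   dimnames = list(NULL, c("a", "c"))), 1L)
  expect_error(zscore_apply(st, bad), "do not match")
})

test_that("classifier config exposes the documented defaults", {
  cfg <- classifier_config()
  expect_equal(cfg$learning_rate, 0.1)
  expect_equal(cfg$n_estimators, 1000L)
  expect_equal(cfg$max_depth, 8L)
  expect_equal(cfg$min_child_weight, 1)
  expect_equal(cfg$gamma, 0)
  expect_equal(cfg$subsample, 0.8)
  expect_equal(cfg$colsample_bytree, 0.8)
  expect_equal(cfg$objective, "binary:logistic")
  expect_equal(cfg$scale_pos_weight, 0.6)
})

test_that("training is deterministic and separates separable data", {
  tb <- blob_table(100, 100, d = 5, sep = 4, seed = 61)
  cfg <- classifier_config(n_estimators = 50L, seed = 7L)
  m1 <- train_classifier(tb, cfg)
  m2 <- train_classifier(tb, cfg)
  p1 <- predict_classifier(m1, tb)
  p2 <- predict_classifier(m2, tb)
  expect_identical(p1, p2)                       # single thread, same seed
  expect_equal(oracle_auc(tb$y, p1), 1)          # separable blobs

  one <- feature_table(tb$ids, tb$X, rep(1L, 200))
  expect_error(train_classifier(one, cfg), "both classes")
  nan <- tb; nan$X[1, 1] <- NaN
  expect_error(train_classifier(nan, cfg), "non-finite")
  wrong <- feature_table(tb$ids, tb$X[, 1:3], tb$y)
  expect_error(predict_classifier(m1, wrong), "do not match")
})

test_that("confusion counts enumerate all four cells", {
  expect_equal(confusion(c(1, 1, 0, 0), c(1, 0, 0, 1)),
               list(tp = 1L, fp = 1L, tn = 1L, fn = 1L))
  perfect <- confusion(c(1, 0, 1), c(1, 0, 1))
  expect_equal(perfect$fp + perfect$fn, 0L)
  allpos <- confusion(c(rep(1, 3), rep(0, 7)), rep(1, 10))
  expect_equal(allpos, list(tp = 3L, fp = 7L, tn = 0L, fn = 0L))
  expect_error(confusion(c(1, 0), c(1)), "length")
})

test_that("the metric suite evaluates the printed formulas", {
  r <- metric_suite(25, 25, 25, 25)
  expect_equal(r$acc, 0.5)
  expect_equal(r$mcc, 0)
  expect_equal(r$paper_auc, 0.5)

  rp <- metric_suite(10, 0, 10, 0)
  expect_equal(c(rp$acc, rp$sens, rp$spec, rp$precision, rp$mcc,
                 rp$paper_auc), rep(1, 6))

  o <- oracle_metrics(50, 10, 90, 5)
  rd <- metric_suite(50, 10, 90, 5)
  expect_equal(rd$acc, o$acc)
  expect_equal(rd$sens, o$sens)
  expect_equal(rd$spec, o$spec)
  expect_equal(rd$precision, o$precision)
  expect_equal(rd$mcc, o$mcc)
  expect_equal(rd$paper_auc, o$bacc)

  # empty-class rates are flagged undefined, not silently zero
  ru <- metric_suite(0, 5, 5, 0)   # no true positives in the data
  expect_true(is.nan(ru$sens))
  rv <- metric_suite(0, 0, 5, 5)   # no positive predictions
  expect_true(is.nan(rv$precision))
  expect_equal(ru$mcc, 0)
  expect_equal(rv$mcc, 0)
})

test_that("ROC area matches the rank-statistic oracle and the two-point identity", {
  set.seed(62)
  y <- rep(0:1, 40)
  s <- stats::runif(80) + 0.3 * y
  cm <- confusion(y, as.integer(s >= 0.5))
  r <- metric_suite(cm$tp, cm$fp, cm$tn, cm$fn, scores = s, labels = y)
  expect_equal(r$roc_auc, oracle_auc(y, s), tolerance = 1e-12)

  # scores that are the binary predictions themselves: ROC has two points
  # and its trapezoid equals (Sens + Spec)/2
  p <- as.integer(s >= 0.5)
  r2 <- metric_suite(cm$tp, cm$fp, cm$tn, cm$fn, scores = p, labels = y)
  expect_equal(r2$roc_auc, r2$paper_auc, tolerance = 1e-12)
})

test_that("raising the threshold never raises Sens nor lowers Spec", {
  set.seed(63)
  y <- rep(0:1, 50)
  s <- stats::runif(100) + 0.4 * y
  prev <- NULL
  for (th in seq(0.1, 0.9, by = 0.1)) {
    cm <- confusion(y, as.integer(s >= th))
    r <- metric_suite(cm$tp, cm$fp, cm$tn, cm$fn, threshold = th)
    if (!is.null(prev)) {
      expect_lte(r$sens, prev$sens + 1e-12)
      expect_gte(r$spec, prev$spec - 1e-12)
    }
    prev <- r
  }
})

test_that("repeated CV is seed-reproducible and signal-sensitive", {
  cfg <- classifier_config(n_estimators = 60L)
  tb <- blob_table(60, 60, d = 5, sep = 2, seed = 64)
  a <- run_cv(tb, k = 5, config = cfg, repeats = 1, seed = 2)
  b <- run_cv(tb, k = 5, config = cfg, repeats = 1, seed = 2)
  expect_identical(a$report, b$report)
  expect_gte(a$report$roc_auc, 0.9)
  expect_length(a$per_fold, 5L)

  # label permutation: CV ROC-AUC collapses to chance
  set.seed(65)
  null_tb <- feature_table(tb$ids, tb$X, sample(tb$y))
  nr <- run_cv(null_tb, k = 5, config = cfg, repeats = 1, seed = 2)
  expect_gt(nr$report$roc_auc, 0.35)
  expect_lt(nr$report$roc_auc, 0.65)
})

test_that("holdout evaluation fits everything on training data only", {
  tr <- blob_table(80, 80, d = 5, sep = 3, seed = 66)
  te <- blob_table(40, 40, d = 5, sep = 3, seed = 67)
  te$ids <- paste0("t", seq_along(te$ids))
  cfg <- classifier_config(n_estimators = 60L)
  rep_ <- evaluate_holdout(tr, te, cfg)
  expect_gte(rep_$roc_auc, 0.95)
  expect_equal(rep_$tp + rep_$fp + rep_$tn + rep_$fn, 80L)

  # CV estimate and holdout agree on data from the same generator
  cv <- run_cv(tr, k = 5, config = cfg, repeats = 1, seed = 5)
  expect_lt(abs(cv$report$roc_auc - rep_$roc_auc), 0.05)

  expect_error(evaluate_holdout(tr, tr, cfg), "share ids")
})
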