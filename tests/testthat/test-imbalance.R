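test_that("ENN keeps clean neighbourhoods and removes surrounded majority points", {
  # two well-separated blobs: every neighbourhood agrees, zero removals
  tb <- blob_table(20, 40, d = 2, sep = 30, seed = 21)
  out <- enn_undersample(tb)
  expect_equal(out$ids, tb$ids)

  # one majority point dropped centrally among minority points
  X <- rbind(c(0, 0), c(0.1, 0), c(-0.1, 0), c(0, 0.1), c(50, 50),
             c(51, 50), c(50, 51), c(51, 51))
  colnames(X) <- c("f1", "f2")
  tb2 <- feature_table(paste0("s", 1:8), X, c(0L, 1L, 1L, 1L, 0L, 0L, 0L, 0L))
  out2 <- enn_undersample(tb2, n_neighbors = 3L, kind = "all")
  expect_false("s1" %in% out2$ids)
  expect_true(all(paste0("s", 2:8) %in% out2$ids))

  expect_error(enn_undersample(blob_table(5, 0, seed = 1)), "both classes")
})

test_that("ENN agrees with a brute-force per-point kNN reference", {
  tb <- blob_table(80, 120, d = 4, sep = 1, seed = 22)  # overlapping blobs
  for (kind in c("all", "mode")) {
    out <- enn_undersample(tb, n_neighbors = 3L, kind = kind)
    keep <- oracle_enn_keep(tb$X, tb$y, 3L, kind)
    expect_identical(out$ids, tb$ids[keep])
  }
})

test_that("ENN only deletes, only from the majority, and tracks overlap", {
  removed <- vapply(c(4, 1.5, 0.5), function(sep) {
    tb <- blob_table(50, 100, d = 3, sep = sep, seed = 23)
    out <- enn_undersample(tb)
    expect_true(all(out$ids %in% tb$ids))              # no new rows
    expect_equal(sum(out$y == 1L), 50L)                # minority untouched
    100L - sum(out$y == 0L)
  }, integer(1))
  # more class overlap (smaller separation) -> more majority removals
  expect_true(all(diff(removed) > 0))
})

test_that("random undersampling deletes majority rows to the target ratio", {
  tb <- blob_table(3, 9, seed = 24)
  out <- random_undersample(tb, target_ratio = 1, seed = 7)
  expect_equal(c(sum(out$y == 1L), sum(out$y == 0L)), c(3L, 3L))
  out2 <- random_undersample(tb, target_ratio = 1, seed = 7)
  expect_identical(out$ids, out2$ids)                  # seed-reproducible
  expect_true(all(out$ids %in% tb$ids))                # deletion only
  rows_in <- apply(out$X, 1, function(r)
    any(apply(tb$X, 1, function(s) all(s == r))))
  expect_true(all(rows_in))
  expect_error(random_undersample(tb, target_ratio = 0.1), "not reachable")
})

test_that("SMOTE interpolates on minority segments and counts add up", {
  # degenerate: identical minority points -> synthetic copies of them
  X <- rbind(matrix(1, 6, 3), matrix(stats::rnorm(60, 5), 20, 3))
  colnames(X) <- paste0("f", 1:3)
  tb <- feature_table(paste0("s", 1:26), X, c(rep(1L, 6), rep(0L, 20)))
  out <- smote_oversample(tb, n_new = 10, k_neighbors = 5, seed = 3)
  synth <- out$X[grepl("^smote_", out$ids), ]
  expect_true(all(synth == 1))

  tb2 <- blob_table(30, 100, d = 3, sep = 2, seed = 25)
  out2 <- smote_oversample(tb2, n_new = 40, k_neighbors = 5, seed = 4)
  expect_equal(sum(out2$y == 1L), 70L)
  expect_equal(sum(out2$y == 0L), 100L)
  synth2 <- out2$X[grepl("^smote_", out2$ids), ]
  minor <- tb2$X[tb2$y == 1L, ]
  lo <- apply(minor, 2, min); hi <- apply(minor, 2, max)
  # interpolation stays inside the minority bounding box (convex hull subset)
  expect_true(all(t(synth2) >= lo - 1e-12 & t(synth2) <= hi + 1e-12))

  expect_error(smote_oversample(tb2, 10, k_neighbors = 40), "exceed")
})

test_that("SMOTE at benchmark scale grows the minority by the requested count", {
  set.seed(26)
  X <- matrix(stats::rnorm((2214 + 3000) * 2), ncol = 2)
  colnames(X) <- c("f1", "f2")
  tb <- feature_table(paste0("s", seq_len(nrow(X))), X,
                      c(rep(1L, 2214), rep(0L, 3000)))
  out <- smote_oversample(tb, n_new = 5300, k_neighbors = 5, seed = 9)
  expect_equal(sum(out$y == 1L), 7514L)  # 2214 + 5300
})

test_that("resampled folds keep validation data untouched and partitioned", {
  tb <- blob_table(40, 80, d = 3, sep = 1, seed = 27)

  # identity resampler reduces to ordinary stratified k-fold
  folds <- make_resampled_folds(tb, k = 5, resampler = NULL, seed = 1)
  val_ids <- unlist(lapply(folds, function(f) f$validation$ids))
  expect_setequal(val_ids, tb$ids)
  expect_equal(length(val_ids), length(tb$ids))  # each id exactly once
  for (f in folds) {
    expect_length(intersect(f$train$ids, f$validation$ids), 0L)
    # stratification: class ratio preserved within one sample
    expect_lte(abs(sum(f$validation$y) - 40 / 5), 1)
  }

  # SMOTE inside folds: synthetic rows never reach validation
  sm <- function(t) smote_oversample(t, n_new = 30, seed = 2)
  folds_sm <- make_resampled_folds(tb, k = 5, resampler = sm, seed = 1)
  for (f in folds_sm) {
    expect_true(any(grepl("^smote_", f$train$ids)))
    expect_false(any(grepl("^smote_", f$validation$ids)))
    expect_true(all(f$validation$ids %in% tb$ids))
  }

  # ENN inside folds: validation folds still partition the input exactly
  folds_enn <- make_resampled_folds(tb, k = 5,
                                    resampler = enn_undersample, seed = 3)
  ids <- lapply(folds_enn, function(f) f$validation$ids)
  expect_equal(sum(lengths(ids)), length(tb$ids))
  expect_setequal(unlist(ids), tb$ids)

  expect_error(make_resampled_folds(blob_table(3, 50, seed = 1), k = 5),
               "smaller class")
})

test_that("out-of-scope resampler names fail loudly", {
  expect_error(cluster_centroids_undersample(), "not implemented")
  expect_error(nearmiss_undersample(), "not implemented")
  expect_error(smoteenn_resample(), "not implemented")
  expect_error(smotetomek_resample(), "not implemented")
})
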