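# z-score a matrix with population sd; constant columns map to 0.
.zscore_matrix <- function(X) {
  mu <- colMeans(X)
  sds <- sqrt(colMeans(sweep(X, 2L, mu)^2))
  sds[sds == 0] <- 1
  sweep(sweep(X, 2L, mu), 2L, sds, "/")
}

# index of the k nearest neighbours (Euclidean, excluding self) of every row
.knn_indices <- function(X, k) {
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  t(apply(D, 1L, function(row) order(row)[seq_len(k)]))
}

.majority_label <- function(y) {
  if (sum(y == 1L) > sum(y == 0L)) 1L else 0L
}

#' Edited nearest-neighbours undersampling
#'
#' Removes majority-class samples whose neighbourhood disagrees with their
#' label: with `kind = "all"` a majority sample is dropped as soon as any
#' of its `n_neighbors` nearest neighbours (Euclidean on z-scored
#' features, self excluded) has a different class; with `kind = "mode"`
#' it is dropped when the neighbour majority differs. The minority class
#' is never touched and no rows are synthesized — this is a cleaning
#' undersampler, so the resulting class ratio is a data outcome, not a
#' parameter.
#'
#' @param table A `feature_table` containing both classes.
#' @param n_neighbors Number of neighbours consulted (default 3).
#' @param kind Agreement rule, `"all"` (default) or `"mode"`.
#' @return The filtered `feature_table`.
#' @export
enn_undersample <- function(table, n_neighbors = 3L, kind = c("all", "mode")) {
  stopifnot(inherits(table, "feature_table"))
  kind <- match.arg(kind)
  y <- table$y
  n <- length(y)
  if (length(unique(y)) < 2L)
    stop("ENN requires both classes to be present")
  if (n_neighbors < 1L || n_neighbors >= n)
    stop("n_neighbors must be in [1, n - 1]")
  maj <- .majority_label(y)
  nn <- .knn_indices(.zscore_matrix(table$X), n_neighbors)
  drop <- rep(FALSE, n)
  for (i in which(y == maj)) {
    disagree <- sum(y[nn[i, ]] != y[i])
    drop[i] <- if (kind == "all") disagree > 0L
               else disagree > n_neighbors / 2
  }
  .ft_subset_rows(table, !drop)
}

#' Random undersampling of the majority class
#'
#' Subsamples majority rows without replacement until the
#' minority:majority ratio reaches `target_ratio`; deletion only, never
#' synthesis.
#'
#' @param table A `feature_table` containing both classes.
#' @param target_ratio Desired minority/majority count ratio (1 gives
#'   balanced classes).
#' @param seed Integer RNG seed.
#' @return The subsampled `feature_table` (original row order preserved).
#' @export
random_undersample <- function(table, target_ratio = 1, seed = 1L) {
  stopifnot(inherits(table, "feature_table"), target_ratio > 0)
  y <- table$y
  if (length(unique(y)) < 2L)
    stop("undersampling requires both classes to be present")
  maj <- .majority_label(y)
  n_min <- sum(y != maj)
  n_maj_new <- as.integer(round(n_min / target_ratio))
  maj_idx <- which(y == maj)
  if (n_maj_new > length(maj_idx) || n_maj_new < 1L)
    stop("target_ratio ", target_ratio, " is not reachable by deletion ",
         "(would need ", n_maj_new, " majority rows, have ",
         length(maj_idx), ")")
  set.seed(seed)
  keep <- sort(c(which(y != maj), sample(maj_idx, n_maj_new)))
  .ft_subset_rows(table, keep)
}

#' SMOTE oversampling of the minority class
#'
#' Generates `n_new` synthetic minority rows by uniform interpolation on
#' the segment between a random minority sample and one of its
#' `k_neighbors` minority-class nearest neighbours. Original rows are
#' retained; synthetic rows get ids `smote_1`, `smote_2`, ...
#'
#' @param table A `feature_table` whose minority class has more than
#'   `k_neighbors` members.
#' @param n_new Number of synthetic rows to add.
#' @param k_neighbors Neighbourhood size (default 5).
#' @param seed Integer RNG seed.
#' @return The augmented `feature_table`.
#' @export
smote_oversample <- function(table, n_new, k_neighbors = 5L, seed = 1L) {
  stopifnot(inherits(table, "feature_table"), n_new >= 1L)
  y <- table$y
  if (length(unique(y)) < 2L)
    stop("oversampling requires both classes to be present")
  minor <- 1L - .majority_label(y)
  min_idx <- which(y == minor)
  if (length(min_idx) <= k_neighbors)
    stop("minority class (", length(min_idx),
         ") must exceed k_neighbors (", k_neighbors, ")")
  Xm <- table$X[min_idx, , drop = FALSE]
  nn <- .knn_indices(Xm, k_neighbors)
  set.seed(seed)
  base <- sample(nrow(Xm), n_new, replace = TRUE)
  pick <- nn[cbind(base, sample(k_neighbors, n_new, replace = TRUE))]
  gap <- stats::runif(n_new)
  Xnew <- Xm[base, , drop = FALSE] +
    gap * (Xm[pick, , drop = FALSE] - Xm[base, , drop = FALSE])
  feature_table(c(table$ids, paste0("smote_", seq_len(n_new))),
                rbind(table$X, Xnew),
                c(y, rep(minor, n_new)))
}

#' @rdname resampler_stubs
#' @export
cluster_centroids_undersample <- function(...)
  stop("ClusterCentroids undersampling is not implemented")
#' @rdname resampler_stubs
#' @export
nearmiss_undersample <- function(...)
  stop("NearMiss undersampling is not implemented")
#' @rdname resampler_stubs
#' @export
smoteenn_resample <- function(...)
  stop("SMOTEENN combined resampling is not implemented")
#' Declared but unimplemented resampling interfaces
#'
#' ClusterCentroids, NearMiss, SMOTEENN and SMOTETomek are part of the
#' standard imbalance-handling menu but out of this package's scope; the
#' names exist so pipelines referencing them fail loudly rather than
#' silently.
#'
#' @param ... Ignored.
#' @name resampler_stubs
#' @export
smotetomek_resample <- function(...)
  stop("SMOTETomek combined resampling is not implemented")

#' Stratified cross-validation folds with resampling inside training folds
#'
#' Builds a stratified k-fold partition and, for each fold, applies the
#' resampler to the k-1 training folds ONLY; the validation fold is the
#' untouched original data. Resamplers that synthesize rows (SMOTE) or
#' delete rows (ENN) therefore never contaminate validation data, and the
#' union of validation folds reproduces the input table exactly once.
#'
#' @param table A `feature_table` with both classes.
#' @param k Fold count (>= 2, at most the size of the smaller class).
#' @param resampler `NULL` (identity) or a function `feature_table ->
#'   feature_table` applied to each training split.
#' @param seed Integer RNG seed for the fold assignment.
#' @return List of k elements, each `list(train=, validation=, fold=)`.
#' @export
make_resampled_folds <- function(table, k = 5L, resampler = NULL, seed = 1L) {
  stopifnot(inherits(table, "feature_table"), k >= 2L)
  y <- table$y
  if (min(sum(y == 1L), sum(y == 0L)) < k)
    stop("k = ", k, " exceeds the size of the smaller class")
  set.seed(seed)
  assign <- integer(length(y))
  for (cl in c(0L, 1L)) {
    idx <- sample(which(y == cl))
    assign[idx] <- rep_len(seq_len(k), length(idx))
  }
  lapply(seq_len(k), function(f) {
    train <- .ft_subset_rows(table, assign != f)
    if (!is.null(resampler)) train <- resampler(train)
    list(train = train,
         validation = .ft_subset_rows(table, assign == f),
         fold = f)
  })
}
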