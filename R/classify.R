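#' Fit a z-score standardizer on training data
#'
#' Stores per-feature means and population standard deviations; constant
#' features get sd 1 so they map to 0. Fit on training data only and
#' applied unchanged elsewhere, so no test information leaks into the
#' scaling.
#'
#' @param table A non-empty `feature_table`.
#' @return Object of class `standardizer` with `means` and `sds`.
#' @export
zscore_fit <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (nrow(table$X) == 0L) stop("cannot fit a standardizer on an empty table")
  mu <- colMeans(table$X)
  sds <- sqrt(colMeans(sweep(table$X, 2L, mu)^2))
  sds[sds == 0] <- 1
  structure(list(means = mu, sds = sds, feature_names = table$feature_names),
            class = "standardizer")
}

#' Apply a fitted standardizer
#'
#' @param state A `standardizer` from [zscore_fit()].
#' @param table A `feature_table` with the same feature columns.
#' @return The standardized `feature_table`.
#' @export
zscore_apply <- function(state, table) {
  stopifnot(inherits(state, "standardizer"), inherits(table, "feature_table"))
  if (!identical(state$feature_names, table$feature_names))
    stop("feature columns do not match the fitted standardizer")
  Z <- sweep(sweep(table$X, 2L, state$means), 2L, state$sds, "/")
  feature_table(table$ids, Z, table$y)
}

#' Gradient-boosting classifier configuration
#'
#' Defaults: learning_rate 0.1, n_estimators 1000, max_depth 8,
#' min_child_weight 1, gamma 0, subsample 0.8, colsample_bytree 0.8,
#' binary-logistic objective, scale_pos_weight 0.6 (the positive class is
#' the rarer one even after cleaning undersampling, and this weight keeps
#' the booster from over-favouring it), single thread for bit
#' reproducibility.
#'
#' @param learning_rate Shrinkage per boosting round.
#' @param n_estimators Number of boosting rounds.
#' @param max_depth Maximum tree depth.
#' @param min_child_weight Minimum sum of instance weight in a child.
#' @param gamma Minimum loss reduction to split.
#' @param subsample Row subsample ratio per tree.
#' @param colsample_bytree Column subsample ratio per tree.
#' @param objective Learning objective.
#' @param n_threads Threads (keep 1 for deterministic fits).
#' @param scale_pos_weight Weight multiplier on the positive class.
#' @param seed Integer seed for the booster's RNG.
#' @return Object of class `classifier_config`.
#' @export
classifier_config <- function(learning_rate = 0.1, n_estimators = 1000L,
                              max_depth = 8L, min_child_weight = 1,
                              gamma = 0, subsample = 0.8,
                              colsample_bytree = 0.8,
                              objective = "binary:logistic",
                              n_threads = 1L, scale_pos_weight = 0.6,
                              seed = 1L) {
  structure(list(learning_rate = learning_rate,
                 n_estimators = as.integer(n_estimators),
                 max_depth = as.integer(max_depth),
                 min_child_weight = min_child_weight, gamma = gamma,
                 subsample = subsample, colsample_bytree = colsample_bytree,
                 objective = objective, n_threads = as.integer(n_threads),
                 scale_pos_weight = scale_pos_weight,
                 seed = as.integer(seed)),
            class = "classifier_config")
}

#' Train the gradient-boosted classifier
#'
#' @param table A `feature_table` with both classes and finite features.
#' @param config A [classifier_config()].
#' @return Object of class `vtp_model` holding the booster and the
#'   feature-name contract; prediction on mismatched columns is rejected.
#' @export
train_classifier <- function(table, config = classifier_config()) {
  stopifnot(inherits(table, "feature_table"),
            inherits(config, "classifier_config"))
  if (length(unique(table$y)) < 2L)
    stop("training requires both classes to be present")
  if (!all(is.finite(table$X)))
    stop("training features contain non-finite values")
  dtrain <- xgboost::xgb.DMatrix(table$X, label = table$y)
  params <- list(objective = config$objective,
                 eta = config$learning_rate,
                 max_depth = config$max_depth,
                 min_child_weight = config$min_child_weight,
                 gamma = config$gamma,
                 subsample = config$subsample,
                 colsample_bytree = config$colsample_bytree,
                 nthread = config$n_threads,
                 scale_pos_weight = config$scale_pos_weight,
                 seed = config$seed)
  booster <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = config$n_estimators, verbose = 0)
  structure(list(booster = booster, feature_names = table$feature_names,
                 config = config),
            class = "vtp_model")
}

#' Predict positive-class probabilities
#'
#' @param model A `vtp_model`.
#' @param table A `feature_table` with the same feature columns as the
#'   training data.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_classifier <- function(model, table) {
  stopifnot(inherits(model, "vtp_model"), inherits(table, "feature_table"))
  if (!identical(model$feature_names, table$feature_names))
    stop("feature columns do not match the trained model")
  stats::predict(model$booster, xgboost::xgb.DMatrix(table$X))
}

#' Confusion counts (positive = vesicular = 1)
#'
#' @param labels Binary truth vector.
#' @param predictions Binary prediction vector of equal length.
#' @return Named list `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(labels, predictions) {
  if (length(labels) != length(predictions))
    stop("labels and predictions differ in length")
  labels <- as.integer(labels); predictions <- as.integer(predictions)
  if (!all(labels %in% 0:1) || !all(predictions %in% 0:1))
    stop("labels and predictions must be binary")
  list(tp = sum(labels == 1L & predictions == 1L),
       fp = sum(labels == 0L & predictions == 1L),
       tn = sum(labels == 0L & predictions == 0L),
       fn = sum(labels == 1L & predictions == 0L))
}

#' Evaluation metric suite from confusion counts
#'
#' Computes ACC, sensitivity, specificity, precision and the Matthews
#' correlation coefficient from the counts, the balanced-accuracy
#' summary `paper_auc = (Sens + Spec)/2` reported under that name by the
#' method's evaluation protocol, and (when continuous scores are given)
#' the true trapezoidal ROC area `roc_auc`, labeled separately since the
#' two differ whenever the score threshold sweep is informative. A rate
#' with an empty denominator is `NaN` (undefined, not silently 0); MCC
#' returns 0 when any factor of its denominator is 0.
#'
#' @param tp,fp,tn,fn Confusion counts.
#' @param scores Optional continuous scores (for `roc_auc`).
#' @param labels Optional binary labels aligned with `scores`.
#' @param threshold Decision threshold recorded in the report.
#' @return Object of class `eval_report`.
#' @export
metric_suite <- function(tp, fp, tn, fn, scores = NULL, labels = NULL,
                         threshold = 0.5) {
  n <- tp + fp + tn + fn
  if (n < 1L) stop("empty confusion table")
  rate <- function(num, den) if (den == 0) NaN else num / den
  acc <- (tp + tn) / n
  sens <- rate(tp, tp + fn)
  spec <- rate(tn, fp + tn)
  precision <- rate(tp, tp + fp)
  mcc_den <- sqrt((tp + fp) * (tp + fn)) * sqrt((tn + fp) * (tn + fn))
  mcc <- if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den
  roc_auc <- NA_real_
  if (!is.null(scores) && !is.null(labels)) {
    roc_auc <- as.numeric(pROC::auc(pROC::roc(
      response = as.integer(labels), predictor = as.numeric(scores),
      levels = c(0, 1), direction = "<", quiet = TRUE)))
  }
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 acc = acc, sens = sens, spec = spec,
                 precision = precision, mcc = mcc,
                 paper_auc = (sens + spec) / 2,
                 roc_auc = roc_auc, threshold = threshold),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("<eval_report> tp=%s fp=%s tn=%s fn=%s\n",
                     "  ACC=%.3f Sens=%.3f Spec=%.3f Prec=%.3f ",
                     "MCC=%.3f bAcc=%.3f ROC-AUC=%s\n"),
              format(x$tp), format(x$fp), format(x$tn), format(x$fn),
              x$acc, x$sens, x$spec, x$precision, x$mcc, x$paper_auc,
              ifelse(is.na(x$roc_auc), "NA", sprintf("%.3f", x$roc_auc))))
  invisible(x)
}

.metric_fields <- c("tp", "fp", "tn", "fn", "acc", "sens", "spec",
                    "precision", "mcc", "paper_auc", "roc_auc")

.average_reports <- function(reports) {
  avg <- lapply(.metric_fields, function(f)
    mean(vapply(reports, function(r) as.numeric(r[[f]]), numeric(1))))
  names(avg) <- .metric_fields
  avg$threshold <- reports[[1]]$threshold
  structure(avg, class = "eval_report")
}

#' Repeated stratified cross-validation of the full pipeline
#'
#' For each repeat, [make_resampled_folds()] builds a stratified
#' partition in which the resampler touches training folds only. Inside
#' every training split the standardizer, the optional feature selector
#' and the classifier are fitted from scratch; the untouched validation
#' fold is scored at the decision threshold. Per-fold metric reports are
#' averaged over folds, then over repeats (repeats use seeds `seed`,
#' `seed + 1`, ...).
#'
#' @param table A `feature_table`.
#' @param k Fold count.
#' @param config A [classifier_config()].
#' @param resampler Optional resampling function for training splits.
#' @param selector Optional function `feature_table -> integer indices`
#'   fitted on each (resampled, standardized) training split; the
#'   returned columns are used for training and validation.
#' @param repeats Number of CV repetitions (default 3).
#' @param seed Base RNG seed.
#' @param threshold Decision threshold on the predicted probability.
#' @return List with `report` (averaged `eval_report`), `per_repeat`
#'   (averaged per repeat) and `per_fold` (every fold's report).
#' @export
run_cv <- function(table, k = 5L, config = classifier_config(),
                   resampler = NULL, selector = NULL, repeats = 3L,
                   seed = 1L, threshold = 0.5) {
  stopifnot(repeats >= 1L)
  per_fold <- list()
  per_repeat <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    folds <- make_resampled_folds(table, k, resampler, seed = seed + r - 1L)
    fold_reports <- lapply(folds, function(fd) {
      st <- zscore_fit(fd$train)
      tr <- zscore_apply(st, fd$train)
      va <- zscore_apply(st, fd$validation)
      if (!is.null(selector)) {
        keep <- selector(tr)
        tr <- .ft_subset_cols(tr, keep)
        va <- .ft_subset_cols(va, keep)
      }
      cfg <- config
      cfg$seed <- config$seed + r - 1L
      model <- train_classifier(tr, cfg)
      p <- predict_classifier(model, va)
      cm <- confusion(va$y, as.integer(p >= threshold))
      metric_suite(cm$tp, cm$fp, cm$tn, cm$fn, scores = p, labels = va$y,
                   threshold = threshold)
    })
    per_fold <- c(per_fold, fold_reports)
    per_repeat[[r]] <- .average_reports(fold_reports)
  }
  list(report = .average_reports(per_repeat),
       per_repeat = per_repeat, per_fold = per_fold)
}

#' Train on one table, evaluate once on a disjoint holdout
#'
#' The full pipeline (resample, z-score, select, train) is fitted on the
#' training table only; the test table is scored untouched at the
#' decision threshold. Overlapping sample ids are an error — the id audit
#' is what guarantees no test row influences any fitted component.
#'
#' @param train_table,test_table `feature_table`s with disjoint ids and
#'   identical feature columns.
#' @param config A [classifier_config()].
#' @param resampler Optional resampler applied to the training table.
#' @param selector Optional selector `feature_table -> integer indices`.
#' @param threshold Decision threshold (default 0.5).
#' @return An `eval_report` for the holdout.
#' @export
evaluate_holdout <- function(train_table, test_table,
                             config = classifier_config(),
                             resampler = NULL, selector = NULL,
                             threshold = 0.5) {
  stopifnot(inherits(train_table, "feature_table"),
            inherits(test_table, "feature_table"))
  overlap <- intersect(train_table$ids, test_table$ids)
  if (length(overlap) > 0L)
    stop("train and test tables share ids (e.g. '", overlap[1], "')")
  if (!is.null(resampler)) train_table <- resampler(train_table)
  st <- zscore_fit(train_table)
  tr <- zscore_apply(st, train_table)
  te <- zscore_apply(st, test_table)
  if (!is.null(selector)) {
    keep <- selector(tr)
    tr <- .ft_subset_cols(tr, keep)
    te <- .ft_subset_cols(te, keep)
  }
  model <- train_classifier(tr, config)
  p <- predict_classifier(model, te)
  cm <- confusion(te$y, as.integer(p >= threshold))
  metric_suite(cm$tp, cm$fp, cm$tn, cm$fn, scores = p, labels = te$y,
               threshold = threshold)
}

#' Export ROC curve points for external plotting
#'
#' @param labels Binary labels.
#' @param scores Continuous scores.
#' @param path Optional CSV path; when given the points are written there.
#' @return Data frame with columns `threshold`, `sensitivity`,
#'   `specificity` (invisibly when `path` is given).
#' @export
roc_points <- function(labels, scores, path = NULL) {
  r <- pROC::roc(response = as.integer(labels),
                 predictor = as.numeric(scores),
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  df <- data.frame(threshold = r$thresholds, sensitivity = r$sensitivities,
                   specificity = r$specificities)
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' Serialize an evaluation report to JSON
#'
#' @param report An `eval_report`.
#' @param path Output path.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
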