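#' Construct a labeled feature table
#'
#' @param ids Character vector of sample identifiers (unique).
#' @param X Numeric n x d matrix with feature names as column names.
#' @param y Binary integer labels (1 = vesicular transport protein).
#' @return Object of class `feature_table` with fields `ids`, `X`, `y`
#'   and `feature_names`.
#' @export
feature_table <- function(ids, X, y) {
  X <- as.matrix(X)
  ids <- as.character(ids)
  y <- as.integer(y)
  if (length(ids) != nrow(X) || length(y) != nrow(X))
    stop("ids, X and y must have matching row counts")
  if (anyDuplicated(ids)) stop("sample ids must be unique")
  if (!all(y %in% c(0L, 1L))) stop("labels must be binary 0/1")
  if (is.null(colnames(X)))
    colnames(X) <- paste0("f", seq_len(ncol(X)))
  structure(list(ids = ids, X = X, y = y, feature_names = colnames(X)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> ", length(x$ids), " samples x ", ncol(x$X),
      " features (", sum(x$y), " positive)\n", sep = "")
  invisible(x)
}

#' Dimensions of a feature table (samples x features)
#' @param x A `feature_table`.
#' @export
dim.feature_table <- function(x) dim(x$X)

.ft_subset_rows <- function(table, idx) {
  feature_table(table$ids[idx], table$X[idx, , drop = FALSE], table$y[idx])
}

.ft_subset_cols <- function(table, idx) {
  feature_table(table$ids, table$X[, idx, drop = FALSE], table$y)
}

#' Extract a feature table from labeled PSSM profiles
#'
#' Normalizes each raw profile with the logistic map, applies the chosen
#' encoder(s) and stacks the resulting vectors. With `encoder = "both"`
#' the 420 AATP columns come first and the 700 CSP-SegPseP-SegACP columns
#' second (1,120 in total).
#'
#' @param profiles List of `pssm_profile`s (raw or already normalized).
#' @param labels Binary labels aligned with `profiles`.
#' @param encoder One of `"both"`, `"aatp"`, `"csp"`.
#' @return A `feature_table`.
#' @export
extract_features <- function(profiles, labels,
                             encoder = c("both", "aatp", "csp")) {
  encoder <- match.arg(encoder)
  enc <- switch(encoder,
                aatp = aatp,
                csp  = csp_segpsep_segacp,
                both = function(p) c(aatp(p), csp_segpsep_segacp(p)))
  rows <- lapply(profiles, function(p) {
    if (!p$normalized) p <- normalize_pssm(p)
    enc(p)
  })
  X <- do.call(rbind, rows)
  feature_table(vapply(profiles, `[[`, character(1), "id"), X, labels)
}

#' Write a feature table to CSV
#'
#' Columns: `id`, `label`, then one column per feature.
#'
#' @param table A `feature_table`.
#' @param path Output path.
#' @export
write_feature_csv <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  df <- data.frame(id = table$ids, label = table$y, table$X,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_csv()]
#'
#' @param path CSV path with `id` and `label` columns.
#' @return A `feature_table`.
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("id", "label") %in% names(df)))
    stop("feature CSV must have 'id' and 'label' columns: ", path)
  feats <- setdiff(names(df), c("id", "label"))
  feature_table(df$id, as.matrix(df[, feats, drop = FALSE]), df$label)
}
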