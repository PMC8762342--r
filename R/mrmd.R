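#' Max-Relevance scores: absolute Pearson correlation with the label
#'
#' @param table A `feature_table` with n >= 3 rows and non-constant labels.
#' @return Numeric vector of length d in `[0, 1]`; constant features
#'   score 0.
#' @export
relevance_scores <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (nrow(table$X) < 3L) stop("relevance requires n >= 3 samples")
  if (length(unique(table$y)) < 2L)
    stop("labels are constant; relevance undefined")
  r <- suppressWarnings(abs(as.vector(stats::cor(table$X, table$y))))
  r[is.na(r)] <- 0
  r
}

#' Max-Distance scores: mean inter-feature Euclidean distance
#'
#' For each feature, the mean Euclidean distance between its column vector
#' and every other feature column, rescaled to `[0, 1]` by the maximum.
#' Higher means less redundant. Columns are used as given; callers that
#' want scale-free distances (as [rank_features()] does) z-score first.
#'
#' @param table A `feature_table` with d >= 2 features.
#' @return Numeric vector of length d in `[0, 1]`.
#' @export
distance_scores <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  d <- ncol(table$X)
  if (d < 2L) stop("distance scores require d >= 2 features")
  D <- as.matrix(stats::dist(t(table$X)))
  s <- rowSums(D) / (d - 1L)
  mx <- max(s)
  if (mx > 0) s / mx else s
}

.mrmd_methods <- c("hits_a", "hits_h", "pagerank", "trustrank",
                   "leaderrank", "score_sum")

# Directed preference graph over features: edge u -> v whenever v beats u
# on at least one base ordering (relevance, distance, relevance + distance),
# weighted by the total victory margin sum_o max(0, s_o(v) - s_o(u)). Edges
# point from loser to winner ("endorsement"), so in-centrality measures
# quality, and decisive wins count for more than marginal ones.
.preference_graph <- function(rel, dst) {
  sums <- rel + dst
  margin <- function(s) pmax(outer(s, s, function(a, b) b - a), 0)
  W <- margin(rel) + margin(dst) + margin(sums)
  igraph::graph_from_adjacency_matrix(W, mode = "directed", weighted = TRUE)
}

#' Rank features by Max-Relevance-Max-Distance
#'
#' Features are scored by relevance (|Pearson r| with the label, computed
#' on z-scored columns) and distance (mean inter-feature Euclidean
#' distance, z-scored columns). `score_sum` ranks by relevance + distance
#' directly. The five link-analysis aggregations build a directed
#' preference graph with an edge u -> v (weighted by how many of the
#' relevance / distance / sum orderings v wins against u) and rank by the
#' corresponding centrality: PageRank (damping 0.85), TrustRank
#' (personalized PageRank restarted at the top relevance decile),
#' LeaderRank (PageRank on the graph augmented with a bidirectionally
#' connected ground node), HITS authority descending (`hits_a`), and HITS
#' hub ascending (`hits_h`; on the endorsement orientation the hub score
#' measures how strongly a feature endorses better ones, i.e. how often
#' it loses, so low hub means good). Ties are broken by relevance, then
#' feature index.
#'
#' @param table A `feature_table` (n >= 3, d >= 2).
#' @param method One of `"hits_a"`, `"hits_h"`, `"pagerank"`,
#'   `"trustrank"`, `"leaderrank"`, `"score_sum"`.
#' @return Object of class `feature_ranking` with fields `order` (best
#'   first), `relevance`, `distance`, `score`, `method`.
#' @export
rank_features <- function(table, method = "score_sum") {
  stopifnot(inherits(table, "feature_table"))
  if (!method %in% .mrmd_methods)
    stop("unknown MRMD method '", method, "'; use one of: ",
         paste(.mrmd_methods, collapse = ", "))
  zt <- feature_table(table$ids, .zscore_matrix(table$X), table$y)
  rel <- relevance_scores(zt)
  dst <- distance_scores(zt)
  d <- length(rel)
  ascending <- FALSE
  if (method == "score_sum") {
    score <- rel + dst
  } else {
    g <- .preference_graph(rel, dst)
    w <- igraph::E(g)$weight
    score <- switch(method,
      pagerank = igraph::page_rank(g, damping = 0.85, weights = w)$vector,
      trustrank = {
        seeds <- order(-rel)[seq_len(max(1L, ceiling(d / 10)))]
        pers <- numeric(d); pers[seeds] <- 1 / length(seeds)
        igraph::page_rank(g, damping = 0.85, weights = w,
                          personalized = pers)$vector
      },
      leaderrank = {
        # ground node bidirectionally tied to every feature
        gl <- igraph::add_vertices(g, 1L)
        edges <- rbind(cbind(d + 1L, seq_len(d)), cbind(seq_len(d), d + 1L))
        gl <- igraph::add_edges(gl, t(edges), weight = 1)
        pr <- igraph::page_rank(gl, damping = 0.85,
                                weights = igraph::E(gl)$weight)$vector
        pr[seq_len(d)]
      },
      hits_a = .hits(g)$authority,
      hits_h = { ascending <- TRUE; .hits(g)$hub })
  }
  key <- if (ascending) score else -score
  ord <- order(key, -rel, seq_len(d))
  structure(list(order = ord, relevance = rel, distance = dst,
                 score = as.numeric(score), method = method),
            class = "feature_ranking")
}

.hits <- function(g) {
  if ("hits_scores" %in% getNamespaceExports("igraph")) {
    s <- igraph::hits_scores(g, scale = TRUE)
    list(authority = s$authority, hub = s$hub)
  } else {
    list(authority = igraph::authority_score(g)$vector,
         hub = igraph::hub_score(g)$vector)
  }
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat("<feature_ranking> method=", x$method, " d=", length(x$order),
      " top: ", paste(utils::head(x$order, 5L), collapse = ", "),
      "...\n", sep = "")
  invisible(x)
}

#' Choose the best top-k feature subset along a ranking
#'
#' Evaluates a cross-validated metric callback on each top-k prefix of
#' the ranking and returns the k that maximizes it (ties favour the
#' smaller k), with the full score curve.
#'
#' @param table A `feature_table`.
#' @param ranking A `feature_ranking` for the same features.
#' @param evaluator Function `feature_table -> numeric` returning the
#'   metric to maximize (e.g. mean CV ROC-AUC).
#' @param k_grid Integer vector of candidate sizes (<= d); default every
#'   10th dimension from 20 up to d.
#' @param metric_name Label stored with the result.
#' @return Object of class `subset_search_result` with `selected`
#'   (feature indices, a prefix of the ranking), `k`, `score_curve`
#'   (data frame k/score) and `metric_name`.
#' @export
select_subset <- function(table, ranking, evaluator, k_grid = NULL,
                          metric_name = "metric") {
  stopifnot(inherits(table, "feature_table"),
            inherits(ranking, "feature_ranking"))
  d <- ncol(table$X)
  if (is.null(k_grid))
    k_grid <- if (d >= 20L) unique(c(seq(20L, d, by = 10L), d)) else d
  k_grid <- sort(unique(as.integer(k_grid)))
  if (length(k_grid) == 0L || any(k_grid < 1L) || any(k_grid > d))
    stop("k_grid must be nonempty with values in [1, d]")
  scores <- vapply(k_grid, function(k) {
    sub <- .ft_subset_cols(table, ranking$order[seq_len(k)])
    val <- tryCatch(evaluator(sub),
                    error = function(e) stop("evaluator failed at k = ", k,
                                             ": ", conditionMessage(e)))
    as.numeric(val)
  }, numeric(1))
  best <- which.max(scores)  # first max = smallest k on ties
  structure(list(selected = ranking$order[seq_len(k_grid[best])],
                 k = k_grid[best],
                 score_curve = data.frame(k = k_grid, score = scores),
                 metric_name = metric_name),
            class = "subset_search_result")
}

#' Serialize a ranking or subset-search result to JSON
#'
#' @param x A `feature_ranking` or `subset_search_result`.
#' @param path Output path.
#' @export
write_ranking_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
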