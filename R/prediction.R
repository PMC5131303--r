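# Train/probe splitting and top-L link selection, including the two-budget
# selection rule that reserves part of the prediction list for candidate
# pairs without common neighbours.

#' Randomly split the edges of a graph into training and probe sets
#'
#' Hides a uniform random sample of `round(probe_fraction * m)` edges as the
#' probe set (the "missing links" used as gold standard) and keeps the rest
#' as the training graph. No connectivity constraint is imposed on the
#' training graph.
#'
#' @param g An undirected simple `igraph` graph with at least 2 edges.
#' @param probe_fraction Fraction of edges to hide, strictly between 0 and 1.
#' @param seed Optional integer seed for a reproducible split.
#' @return An object of class `edge_split`: a list with elements `graph` (the
#'   full graph), `training` (igraph with probe edges deleted), `probe`
#'   (two-column character matrix of hidden edges), `probe_fraction`, `seed`.
#' @examples
#' sp <- split_edges(karate_club(), 0.1, seed = 1)
#' nrow(sp$probe) # 8
#' @export
split_edges <- function(g, probe_fraction, seed = NULL) {
  g <- as_cnd_graph(g)
  m <- igraph::ecount(g)
  if (m < 2) stop("graph must have at least 2 edges", call. = FALSE)
  if (probe_fraction <= 0 || probe_fraction >= 1) {
    stop("probe_fraction must be in (0, 1)", call. = FALSE)
  }
  n_probe <- round_half_up(probe_fraction * m)
  n_probe <- max(1L, min(m - 1L, as.integer(n_probe)))
  probe_idx <- with_seed(seed, sample.int(m, n_probe))
  el <- igraph::as_edgelist(g)
  probe <- el[probe_idx, , drop = FALSE]
  probe <- cbind(pmin(probe[, 1], probe[, 2]), pmax(probe[, 1], probe[, 2]))
  colnames(probe) <- c("node_i", "node_j")
  structure(
    list(graph = g,
         training = igraph::delete_edges(g, probe_idx),
         probe = probe,
         probe_fraction = probe_fraction,
         seed = seed),
    class = "edge_split"
  )
}

#' @export
print.edge_split <- function(x, ...) {
  cat("edge split:", igraph::ecount(x$training), "training /",
      nrow(x$probe), "probe edges (fraction",
      format(x$probe_fraction), ")\n")
  invisible(x)
}

#' Partition the probe set by common-neighbour status in the training graph
#'
#' A probe link belongs to the with-CN part when its endpoints share at least
#' one neighbour in the training graph, otherwise to the without-CN part. The
#' realised fraction `c_r` of with-CN probe links is the quantity the
#' training-graph CN coefficient ([training_cn_coefficient()]) estimates.
#'
#' @param split An `edge_split` from [split_edges()].
#' @return A list of class `probe_partition` with elements `with_cn`,
#'   `without_cn` (two-column character matrices) and `c_r`.
#' @export
partition_probe <- function(split) {
  stopifnot(inherits(split, "edge_split"))
  probe <- split$probe
  if (nrow(probe) == 0) stop("empty probe set", call. = FALSE)
  gt <- split$training
  A <- igraph::as_adjacency_matrix(gt, sparse = TRUE)
  CNm <- A %*% A
  nm <- igraph::V(gt)$name
  ii <- match(probe[, 1], nm)
  jj <- match(probe[, 2], nm)
  has_cn <- as.numeric(CNm[cbind(ii, jj)]) > 0
  structure(
    list(with_cn = probe[has_cn, , drop = FALSE],
         without_cn = probe[!has_cn, , drop = FALSE],
         c_r = mean(has_cn)),
    class = "probe_partition"
  )
}

#' CN coefficient of the training graph (the plug-in estimator)
#'
#' The fraction of training edges whose endpoints share a neighbour in the
#' training graph. Used as a plug-in estimate of `c_r`, the fraction of probe
#' links with a common neighbour, when allocating prediction budgets.
#'
#' @param split An `edge_split` from [split_edges()].
#' @return A proportion in `[0, 1]`.
#' @export
training_cn_coefficient <- function(split) {
  stopifnot(inherits(split, "edge_split"))
  if (igraph::ecount(split$training) == 0) {
    stop("empty training set", call. = FALSE)
  }
  cn_coefficient(split$training)
}

# Order candidate indices by decreasing score, breaking ties either with a
# supplied numeric key, a random permutation, or canonical pair order.
rank_candidates <- function(score, tie_break, tie_key) {
  n <- length(score)
  tk <- if (!is.null(tie_key)) {
    stopifnot(length(tie_key) == n)
    tie_key
  } else if (tie_break == "random") {
    stats::runif(n)
  } else {
    seq_len(n)
  }
  order(-score, tk)
}

new_prediction <- function(df, method, budget_cn = NA_integer_,
                           budget_nocn = NA_integer_) {
  structure(df, method = method, budget_cn = budget_cn,
            budget_nocn = budget_nocn,
            class = c("link_prediction", "data.frame"))
}

#' Plain top-L link prediction with a similarity index
#'
#' Scores every candidate (non-adjacent) pair of the training graph with the
#' named index, sorts scores non-increasingly and returns the first `L`
#' pairs. Ties are broken by a seedable random permutation within each tied
#' block (unbiased), or lexicographically with `tie_break = "deterministic"`.
#'
#' @param g_train The training `igraph` graph.
#' @param method A similarity method token (see [score_pairs()]).
#' @param L Number of links to predict (at most the number of candidates).
#' @param beta Local-path damping weight, used by `method = "lp"`.
#' @param tie_break `"random"` (default) or `"deterministic"`.
#' @param tie_key Optional numeric vector, one value per candidate pair in
#'   canonical order, overriding the tie-break; lower values win. Supplying
#'   the same key to several methods makes their tied blocks resolve
#'   identically, which keeps method comparisons paired.
#' @return A `link_prediction`: a `data.frame` of `L` rows with columns
#'   `node_i`, `node_j`, `score`, `pool`, and attribute `method`.
#' @export
predict_top_l <- function(g_train, method, L, beta = 0.01,
                          tie_break = c("random", "deterministic"),
                          tie_key = NULL) {
  g_train <- as_cnd_graph(g_train)
  tie_break <- match.arg(tie_break)
  sc <- score_pairs(g_train, method, beta = beta)
  idx <- candidate_index(g_train)
  cn <- compute_scores(g_train, idx$i, idx$j, "cn")$score
  if (L > nrow(sc)) {
    stop("L exceeds the number of candidate pairs", call. = FALSE)
  }
  ord <- rank_candidates(sc$score, tie_break, tie_key)
  take <- ord[seq_len(L)]
  df <- data.frame(node_i = sc$node_i[take], node_j = sc$node_j[take],
                   score = sc$score[take],
                   pool = ifelse(cn[take] > 0, "cn", "nocn"),
                   stringsAsFactors = FALSE)
  new_prediction(df, method)
}

#' Two-budget top-L prediction from common neighbors and distance
#'
#' Allocates `round(cn_prime * L)` predictions to the candidate pairs that
#' have at least one common neighbour (ranked by the CND score, i.e. by CN
#' count) and the remaining budget to the pairs with none (ranked by
#' closeness, shorter training-graph distance first, disconnected pairs
#' last). If one pool has fewer candidates than its budget the shortfall
#' transfers to the other pool, so `L` links are always returned when the
#' candidate universe allows it.
#'
#' @param g_train The training `igraph` graph.
#' @param L Number of links to predict.
#' @param cn_prime Estimated fraction of missing links with a common
#'   neighbour; defaults to the training-graph CN coefficient.
#' @param tie_break,tie_key As in [predict_top_l()].
#' @return A `link_prediction` with attributes `budget_cn` and `budget_nocn`.
#' @examples
#' sp <- split_edges(karate_club(), 0.1, seed = 1)
#' predict_cnd(sp$training, L = nrow(sp$probe))
#' @export
predict_cnd <- function(g_train, L, cn_prime = NULL,
                        tie_break = c("random", "deterministic"),
                        tie_key = NULL) {
  g_train <- as_cnd_graph(g_train)
  tie_break <- match.arg(tie_break)
  if (L < 1) stop("L must be at least 1", call. = FALSE)
  if (is.null(cn_prime)) cn_prime <- cn_coefficient(g_train)
  if (cn_prime < 0 || cn_prime > 1) {
    stop("cn_prime must be in [0, 1]", call. = FALSE)
  }
  sc <- cnd_scores(g_train)
  if (L > nrow(sc)) {
    stop("L exceeds the number of candidate pairs", call. = FALSE)
  }
  budget_cn <- min(as.integer(round_half_up(cn_prime * L)), L)
  budget_nocn <- L - budget_cn

  n <- nrow(sc)
  tk <- if (!is.null(tie_key)) {
    stopifnot(length(tie_key) == n)
    tie_key
  } else if (tie_break == "random") {
    stats::runif(n)
  } else {
    seq_len(n)
  }
  pool_cn <- which(sc$cn > 0)
  pool_nocn <- which(sc$cn == 0)
  ord_cn <- pool_cn[order(-sc$score[pool_cn], tk[pool_cn])]
  ord_nocn <- pool_nocn[order(-sc$score[pool_nocn], tk[pool_nocn])]

  take_cn <- min(budget_cn, length(ord_cn))
  take_nocn <- min(budget_nocn, length(ord_nocn))
  short <- (budget_cn - take_cn) + (budget_nocn - take_nocn)
  if (short > 0) {
    # pool exhausted: transfer the shortfall to the other pool
    message("budget shortfall of ", short, " transferred between pools")
    if (budget_cn - take_cn > 0) {
      take_nocn <- min(take_nocn + short, length(ord_nocn))
    } else {
      take_cn <- min(take_cn + short, length(ord_cn))
    }
  }
  sel <- c(head(ord_cn, take_cn), head(ord_nocn, take_nocn))
  df <- data.frame(node_i = sc$node_i[sel], node_j = sc$node_j[sel],
                   score = sc$score[sel],
                   pool = rep(c("cn", "nocn"), c(take_cn, take_nocn)),
                   stringsAsFactors = FALSE)
  new_prediction(df, "cnd", budget_cn = take_cn, budget_nocn = take_nocn)
}
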