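# Pairwise likelihood scores: eleven classical structural similarity indices
# plus the combined common-neighbors-and-distance (CND) score.

#' @importFrom Matrix Diagonal
NULL

#' Tokens of the implemented similarity methods
#'
#' @return Character vector of the twelve method tokens accepted by
#'   [score_pairs()], [predict_top_l()] and [run_benchmark()].
#' @export
similarity_methods <- function() {
  c("cn", "salton", "jaccard", "sorensen", "hpi", "hdi", "lhn",
    "aa", "ra", "pa", "lp", "cnd")
}

# Vectorised scoring over integer index pairs (ii, jj). Returns list with
# score, cn and (for cnd) distance components.
compute_scores <- function(g, ii, jj, method, beta = 0.01) {
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  k <- igraph::degree(g)
  CNm <- A %*% A
  at <- cbind(ii, jj)
  cn <- as.numeric(CNm[at])
  ki <- k[ii]
  kj <- k[jj]
  safe_div <- function(num, den) ifelse(den > 0, num / ifelse(den > 0, den, 1), 0)
  score <- switch(method,
    cn = cn,
    salton = safe_div(cn, sqrt(ki * kj)),
    jaccard = safe_div(cn, ki + kj - cn),
    sorensen = safe_div(2 * cn, ki + kj),
    hpi = safe_div(cn, pmin(ki, kj)),
    hdi = safe_div(cn, pmax(ki, kj)),
    lhn = safe_div(cn, ki * kj),
    aa = {
      # a common neighbour of a distinct pair has degree >= 2, so 1/log(k)
      # never divides by log(1); degree<2 weights are zeroed defensively
      w <- ifelse(k >= 2, 1 / log(k), 0)
      as.numeric((A %*% Diagonal(x = w) %*% A)[at])
    },
    ra = {
      w <- ifelse(k > 0, 1 / k, 0)
      as.numeric((A %*% Diagonal(x = w) %*% A)[at])
    },
    pa = ki * kj,
    lp = as.numeric((CNm + beta * (CNm %*% A))[at]),
    cnd = NULL,
    stop("unknown similarity method: ", method, call. = FALSE)
  )
  dist <- NULL
  if (method == "cnd") {
    D <- igraph::distances(g, algorithm = "unweighted")
    dist <- D[at]
    score <- cn + ifelse(is.finite(dist), 1 / dist, 0)
  }
  list(score = score, cn = cn, distance = dist)
}

# Resolve a pairs argument (2-column matrix of vertex names, or NULL for all
# candidate pairs) into integer index vectors.
resolve_pairs <- function(g, pairs) {
  if (is.null(pairs)) return(candidate_index(g))
  pairs <- as.matrix(pairs)
  nm <- igraph::V(g)$name
  ii <- match(as.character(pairs[, 1]), nm)
  jj <- match(as.character(pairs[, 2]), nm)
  if (anyNA(ii) || anyNA(jj)) {
    bad <- c(pairs[is.na(ii), 1], pairs[is.na(jj), 2])
    stop("unknown vertex in pairs: ", bad[1], call. = FALSE)
  }
  list(i = ii, j = jj)
}

#' Similarity scores for node pairs
#'
#' Scores node pairs with one of the twelve implemented likelihood indices.
#' With `pairs = NULL` every non-adjacent (candidate) pair is scored, which is
#' the universe used for prediction and AUC evaluation.
#'
#' The neighbourhood indices are, with `CN` the number of common neighbours
#' and `k` the degree: `cn` = CN; `salton` = CN/sqrt(ki kj); `jaccard` =
#' CN/|union of neighbourhoods|; `sorensen` = 2CN/(ki+kj); `hpi` =
#' CN/min(ki,kj); `hdi` = CN/max(ki,kj); `lhn` = CN/(ki kj); `aa` = sum over
#' common neighbours z of 1/log(kz); `ra` = sum of 1/kz; `pa` = ki kj; `lp` =
#' entries of A^2 + beta A^3; `cnd` = CN + 1/d with d the shortest-path
#' distance (1/d taken as 0 for disconnected pairs). Indices whose
#' denominator vanishes (isolated endpoints) score 0.
#'
#' @param g An undirected simple `igraph` graph (typically a training graph).
#' @param method One of `"cn"`, `"salton"`, `"jaccard"`, `"sorensen"`,
#'   `"hpi"`, `"hdi"`, `"lhn"`, `"aa"`, `"ra"`, `"pa"`, `"lp"`, `"cnd"`.
#' @param pairs Optional two-column matrix of vertex names; defaults to all
#'   non-adjacent pairs.
#' @param beta Damping weight of the three-step term in the local-path index
#'   (default 0.01).
#' @return A `data.frame` with columns `node_i`, `node_j`, `score`.
#' @examples
#' g <- karate_club()
#' head(score_pairs(g, "ra"))
#' @export
score_pairs <- function(g, method = similarity_methods(), pairs = NULL,
                        beta = 0.01) {
  g <- as_cnd_graph(g)
  method <- match.arg(method)
  if (method == "cnd") {
    sc <- cnd_scores(g, pairs)
    return(sc[, c("node_i", "node_j", "score")])
  }
  idx <- resolve_pairs(g, pairs)
  res <- compute_scores(g, idx$i, idx$j, method, beta)
  nm <- igraph::V(g)$name
  data.frame(node_i = nm[idx$i], node_j = nm[idx$j], score = res$score,
             stringsAsFactors = FALSE)
}

#' Combined common-neighbors-and-distance score
#'
#' The score of a non-adjacent pair (i, j) is `s = CN_ij + 1/d_ij`, where
#' `CN_ij` is the number of common neighbours and `d_ij` the shortest-path
#' distance in `g` (`1/d = 0` when the pair is disconnected). Pairs with a
#' common neighbour sit at distance 2, so for them `s = CN + 1/2` and the
#' ranking coincides with the plain CN ranking; pairs without a common
#' neighbour are ranked purely by closeness, shorter distance scoring higher,
#' with disconnected pairs last.
#'
#' @param g An undirected simple `igraph` graph.
#' @param pairs Optional two-column matrix of vertex names; defaults to all
#'   non-adjacent pairs. Adjacent pairs are rejected: the score is defined on
#'   candidate (missing-link) pairs only.
#' @return A `data.frame` with columns `node_i`, `node_j`, `cn` (common
#'   neighbour count), `distance` (hop distance, `Inf` if disconnected) and
#'   `score`.
#' @examples
#' g <- igraph::make_graph(~ 1 - 2, 2 - 3, 3 - 4)
#' cnd_scores(g)
#' @export
cnd_scores <- function(g, pairs = NULL) {
  g <- as_cnd_graph(g)
  idx <- resolve_pairs(g, pairs)
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  adj <- as.numeric(A[cbind(idx$i, idx$j)])
  if (any(adj > 0)) {
    stop("cnd score is defined for non-adjacent pairs only", call. = FALSE)
  }
  res <- compute_scores(g, idx$i, idx$j, "cnd")
  nm <- igraph::V(g)$name
  data.frame(node_i = nm[idx$i], node_j = nm[idx$j], cn = res$cn,
             distance = res$distance, score = res$score,
             stringsAsFactors = FALSE)
}
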