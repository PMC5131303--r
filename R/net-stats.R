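# Network statistics used to characterise benchmark graphs and to validate the
# plug-in estimator of the with-common-neighbor probe fraction.

#' Local clustering coefficient of one node
#'
#' Probability that two distinct neighbours of `i` are themselves connected:
#' `2|E_i| / (k_i (k_i - 1))`, where `|E_i|` counts edges among the neighbours
#' of `i`. Defined as 0 for nodes of degree 0 or 1.
#'
#' @param g An undirected simple `igraph` graph.
#' @param i A vertex name (or index).
#' @return A proportion in `[0, 1]`.
#' @export
local_clustering <- function(g, i) {
  g <- as_cnd_graph(g)
  if (is.character(i) && !i %in% igraph::V(g)$name) {
    stop("unknown vertex: ", i, call. = FALSE)
  }
  unname(igraph::transitivity(g, type = "localundirected", vids = i,
                              isolates = "zero"))
}

#' Average local clustering coefficient of a graph
#'
#' Arithmetic mean of [local_clustering()] over all `N` nodes, degree-0/1
#' nodes contributing 0.
#'
#' @param g An undirected simple `igraph` graph with at least one vertex.
#' @return A proportion in `[0, 1]`.
#' @export
clustering_coefficient <- function(g) {
  g <- as_cnd_graph(g)
  if (igraph::vcount(g) == 0) stop("empty graph", call. = FALSE)
  mean(igraph::transitivity(g, type = "localundirected", isolates = "zero"))
}

#' CN coefficient: fraction of edges whose endpoints share a neighbour
#'
#' For every edge (i, j), checks whether the endpoints have at least one
#' common neighbour in the graph itself; the CN coefficient c_n is the
#' fraction of edges for which they do. Applied to a training graph it yields
#' c_n-prime, the plug-in estimate of the fraction of missing links whose
#' endpoints share a neighbour.
#'
#' @param g An undirected simple `igraph` graph with at least one edge.
#' @return A proportion in `[0, 1]`.
#' @export
cn_coefficient <- function(g) {
  g <- as_cnd_graph(g)
  if (igraph::ecount(g) == 0) stop("graph has no edges", call. = FALSE)
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  CN <- A %*% A
  el <- igraph::as_edgelist(g, names = FALSE)
  mean(CN[el] > 0)
}

#' Degree assortativity coefficient
#'
#' Pearson correlation of the degrees at the two ends of an edge, computed
#' over all edges counted in both orientations. Negative values mean
#' high-degree nodes preferentially attach to low-degree nodes.
#'
#' @param g An undirected simple `igraph` graph with at least one edge.
#' @return A correlation in `[-1, 1]`, or `NaN` (with a warning) when every
#'   edge endpoint has the same degree and the statistic is undefined.
#' @export
degree_assortativity <- function(g) {
  g <- as_cnd_graph(g)
  if (igraph::ecount(g) == 0) stop("graph has no edges", call. = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  k <- igraph::degree(g)
  x <- c(k[el[, 1]], k[el[, 2]])
  y <- c(k[el[, 2]], k[el[, 1]])
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("degree assortativity undefined: zero degree variance over edge endpoints",
            call. = FALSE)
    return(NaN)
  }
  stats::cor(x, y)
}

#' Degree heterogeneity
#'
#' The ratio `<k^2> / <k>^2` of the second moment of the degree distribution
#' to the squared mean degree. Equals 1 exactly for regular graphs
#' (Cauchy-Schwarz) and grows with the spread of the degree distribution.
#'
#' @param g An undirected simple `igraph` graph with at least one edge.
#' @return A ratio `>= 1`.
#' @export
degree_heterogeneity <- function(g) {
  g <- as_cnd_graph(g)
  k <- igraph::degree(g)
  if (all(k == 0)) stop("graph has no edges", call. = FALSE)
  mean(k^2) / mean(k)^2
}

#' Average shortest-path distance
#'
#' Mean hop distance over all unordered reachable vertex pairs. Unreachable
#' pairs are excluded from the average (their count is reported as an
#' attribute `n_unreachable`), so the statistic stays finite on disconnected
#' graphs.
#'
#' @param g An undirected `igraph` graph with at least one connected pair.
#' @return Mean distance (numeric), with attribute `n_unreachable`.
#' @export
average_distance <- function(g) {
  g <- as_cnd_graph(g)
  D <- igraph::distances(g, algorithm = "unweighted")
  d <- D[upper.tri(D)]
  fin <- is.finite(d)
  if (!any(fin)) stop("no connected vertex pair", call. = FALSE)
  structure(mean(d[fin]), n_unreachable = sum(!fin))
}

#' Pseudo-distance distribution over edges
#'
#' For each edge e = (i, j), the pseudo-distance is the shortest-path length
#' between i and j in the graph with e removed. Its distribution p_d over the
#' edges measures how many short loops the network contains; the mass at d = 2
#' equals the CN coefficient exactly (an edge with pseudo-distance 2 is an
#' edge whose endpoints share a neighbour). Bridge edges, whose endpoints are
#' disconnected after removal, are tallied in a separate `"Inf"` bin.
#'
#' @param g An undirected simple `igraph` graph with at least one edge.
#' @return A named numeric vector of proportions summing to 1; names are the
#'   pseudo-distance values (`"2"`, `"3"`, ...) plus `"Inf"` for bridges.
#' @export
pseudo_distance_distribution <- function(g) {
  g <- as_cnd_graph(g)
  m <- igraph::ecount(g)
  if (m == 0) stop("graph has no edges", call. = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  d <- vapply(seq_len(m), function(e) {
    h <- igraph::delete_edges(g, e)
    igraph::distances(h, v = el[e, 1], to = el[e, 2],
                      algorithm = "unweighted")[1, 1]
  }, numeric(1))
  tab <- table(d) / m
  out <- as.numeric(tab)
  names(out) <- names(tab)
  out
}

#' Structural profile of a network
#'
#' Bundles the statistics used to characterise benchmark networks: node and
#' edge counts, average local clustering `c`, CN coefficient `c_n`, average
#' distance `<d>`, average degree `<k>`, degree assortativity `r`, and degree
#' heterogeneity `H`.
#'
#' @param g An undirected simple `igraph` graph with at least one edge.
#' @return A one-row `data.frame` with columns `n_nodes`, `n_edges`,
#'   `clustering`, `cn_coefficient`, `mean_distance`, `mean_degree`,
#'   `assortativity`, `heterogeneity`.
#' @examples
#' network_profile(karate_club())
#' @export
network_profile <- function(g) {
  g <- as_cnd_graph(g)
  data.frame(
    n_nodes = igraph::vcount(g),
    n_edges = igraph::ecount(g),
    clustering = clustering_coefficient(g),
    cn_coefficient = cn_coefficient(g),
    mean_distance = as.numeric(average_distance(g)),
    mean_degree = 2 * igraph::ecount(g) / igraph::vcount(g),
    assortativity = degree_assortativity(g),
    heterogeneity = degree_heterogeneity(g)
  )
}

#' Accuracy of the plug-in estimator of the with-CN probe fraction
#'
#' Given paired observations of the training-graph CN coefficient (the
#' estimate) and the realised fraction of probe links with a common neighbour
#' (the estimand), returns their root-mean-square error and Pearson
#' correlation.
#'
#' @param cn_prime Numeric vector of training-graph CN coefficients.
#' @param c_r Numeric vector (same length) of realised probe fractions.
#' @return A list with elements `rmse` and `cc`; `cc` is `NA` when either
#'   vector has zero variance (undefined, not 0 or 1).
#' @export
estimator_diagnostics <- function(cn_prime, c_r) {
  if (length(cn_prime) != length(c_r)) {
    stop("cn_prime and c_r must have the same length", call. = FALSE)
  }
  rmse <- sqrt(mean((cn_prime - c_r)^2))
  cc <- if (length(cn_prime) >= 2 &&
            stats::sd(cn_prime) > 0 && stats::sd(c_r) > 0) {
    stats::cor(cn_prime, c_r)
  } else {
    NA_real_
  }
  list(rmse = rmse, cc = cc)
}
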