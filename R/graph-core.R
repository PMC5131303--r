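#' A fixed suite of synthetic benchmark networks
#'
#' Eight seeded synthetic networks spanning a wide range of CN coefficients
#' (roughly 0.05 to 0.95), mirroring the spread found in classical real-world
#' benchmark collections: three Watts-Strogatz small-world graphs (high to
#' moderate clustering), two Barabasi-Albert scale-free graphs and three
#' Erdos-Renyi graphs (low clustering). Used to study how the training-graph
#' CN coefficient tracks the realised with-CN probe fraction across network
#' types.
#'
#' @param seed Base integer seed; each network derives its own sub-seed.
#' @return A named list of eight undirected simple `igraph` graphs.
#' @export
synthetic_suite <- function(seed = 1) {
  list(
    ws_dense = generate_graph("ws", n = 100, k = 10, p = 0.05, seed = seed + 1),
    ws_mid = generate_graph("ws", n = 150, k = 6, p = 0.1, seed = seed + 2),
    ws_sparse = generate_graph("ws", n = 200, k = 4, p = 0.2, seed = seed + 3),
    ba_dense = generate_graph("ba", n = 100, m = 4, seed = seed + 4),
    ba_sparse = generate_graph("ba", n = 150, m = 2, seed = seed + 5),
    er_dense = generate_graph("er", n = 100, p = 0.08, seed = seed + 6),
    er_mid = generate_graph("er", n = 150, p = 0.04, seed = seed + 7),
    er_sparse = generate_graph("er", n = 200, p = 0.015, seed = seed + 8)
  )
}

#' Hop distances from a single source by breadth-first search
#'
#' @param g An undirected `igraph` graph.
#' @param source A vertex name (or index) present in `g`.
#' @return A named numeric vector of shortest-path hop counts from `source` to
#'   every vertex; unreachable vertices are `Inf`, never a finite sentinel.
#' @examples
#' g <- igraph::make_graph(~ 1 - 2, 2 - 3, 3 - 4)
#' bfs_distances(g, "1")
#' @export
bfs_distances <- function(g, source) {
  g <- as_cnd_graph(g)
  if (is.character(source) && !source %in% igraph::V(g)$name) {
    stop("unknown source vertex: ", source, call. = FALSE)
  }
  d <- igraph::distances(g, v = source, algorithm = "unweighted")[1, ]
  names(d) <- igraph::V(g)$name
  d
}

#' All non-adjacent (candidate) node pairs
#'
#' Enumerates the N(N-1)/2 - m unordered pairs of distinct vertices that are
#' not edges: the universe from which missing links are predicted. Each pair
#' appears once, endpoints sorted, rows ordered canonically.
#'
#' @param g An undirected simple `igraph` graph.
#' @return A two-column character matrix of vertex names, one row per
#'   candidate pair.
#' @export
candidate_pairs <- function(g) {
  g <- as_cnd_graph(g)
  idx <- candidate_index(g)
  nm <- igraph::V(g)$name
  cbind(pmin(nm[idx$i], nm[idx$j]), pmax(nm[idx$i], nm[idx$j]))
}

# Internal: candidate pairs as integer vertex indices (i < j).
candidate_index <- function(g) {
  n <- igraph::vcount(g)
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  dens <- as.matrix(A) != 0
  sel <- upper.tri(dens) & !dens
  w <- which(sel, arr.ind = TRUE)
  list(i = unname(w[, 1]), j = unname(w[, 2]))
}

#' Generate a seeded synthetic benchmark graph
#'
#' Thin, reproducible wrappers around the three classical random-graph models:
#' Erdos-Renyi `G(n, p)`, Barabasi-Albert preferential attachment, and
#' Watts-Strogatz small-world rewiring. Used to exercise predictors and
#' statistics over a controlled range of clustering and degree heterogeneity.
#'
#' @param model One of `"er"`, `"ba"`, `"ws"`.
#' @param n Number of vertices.
#' @param p Edge probability (`er`) or rewiring probability (`ws`).
#' @param m Edges added per new vertex (`ba`).
#' @param k Even ring-lattice degree (`ws`); each vertex starts with `k`
#'   neighbours before rewiring.
#' @param seed Integer seed; the caller's RNG stream is left untouched.
#' @return An undirected simple `igraph` graph with character vertex names.
#' @examples
#' g <- generate_graph("ws", n = 20, k = 4, p = 0, seed = 1)
#' igraph::ecount(g) # 40
#' @export
generate_graph <- function(model = c("er", "ba", "ws"), n, p = NULL, m = NULL,
                           k = NULL, seed = NULL) {
  model <- match.arg(model)
  if (n < 1) stop("n must be positive", call. = FALSE)
  g <- with_seed(seed, switch(model,
    er = {
      if (is.null(p) || p < 0 || p > 1) {
        stop("er model needs edge probability p in [0, 1]", call. = FALSE)
      }
      igraph::sample_gnp(n, p)
    },
    ba = {
      if (is.null(m) || m < 1) {
        stop("ba model needs m >= 1 edges per new vertex", call. = FALSE)
      }
      igraph::sample_pa(n, m = m, directed = FALSE)
    },
    ws = {
      if (is.null(k) || k %% 2 != 0 || k < 2 || k >= n) {
        stop("ws model needs an even ring degree k with 2 <= k < n",
             call. = FALSE)
      }
      if (is.null(p) || p < 0 || p > 1) {
        stop("ws model needs rewiring probability p in [0, 1]", call. = FALSE)
      }
      igraph::sample_smallworld(1, n, k / 2, p)
    }
  ))
  g <- ensure_simple_undirected(g, warn = FALSE)
  igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  g
}
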