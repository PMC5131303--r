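# Small fixture graphs (built in code) and brute-force oracles that stay
# independent of the implementation paths they check.

g_from_edges <- function(...) {
  el <- do.call(rbind, lapply(list(...), as.character))
  igraph::graph_from_edgelist(el, directed = FALSE)
}

g_path4 <- function() g_from_edges(c(1, 2), c(2, 3), c(3, 4))
g_triangle <- function() g_from_edges(c(1, 2), c(2, 3), c(3, 1))
# triangle 1-2-3 with pendant 4 attached to 3
g_tripen <- function() g_from_edges(c(1, 2), c(1, 3), c(2, 3), c(3, 4))
g_star <- function(leaves = 3) {
  g_from_edges_list <- lapply(seq_len(leaves) + 1, function(l) c(1, l))
  do.call(g_from_edges, g_from_edges_list)
}
g_k4 <- function() {
  g_from_edges(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
}
g_cycle4 <- function() g_from_edges(c("a", "b"), c("b", "c"), c("c", "d"), c("d", "a"))

random_test_graph <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- as.character(seq_len(n))
  g
}

# All-pairs shortest paths by Floyd-Warshall on the dense adjacency matrix.
oracle_floyd_warshall <- function(g) {
  n <- igraph::vcount(g)
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  D <- ifelse(A > 0, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  dimnames(D) <- list(igraph::V(g)$name, igraph::V(g)$name)
  D
}

# AUC by explicit enumeration of every (positive, negative) comparison.
oracle_auc <- function(pos, neg) {
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}

# Similarity indices computed directly from neighbour sets, one pair at a
# time, using only base R set operations.
oracle_index <- function(g, u, v, method, beta = 0.01) {
  nm <- igraph::V(g)$name
  nbrs <- function(x) nm[igraph::neighbors(g, x)]
  Ni <- nbrs(u); Nj <- nbrs(v)
  common <- intersect(Ni, Nj)
  cn <- length(common)
  ki <- length(Ni); kj <- length(Nj)
  deg <- function(z) length(nbrs(z))
  div <- function(num, den) if (den > 0) num / den else 0
  switch(method,
    cn = cn,
    salton = div(cn, sqrt(ki * kj)),
    jaccard = div(cn, length(union(Ni, Nj))),
    sorensen = div(2 * cn, ki + kj),
    hpi = div(cn, min(ki, kj)),
    hdi = div(cn, max(ki, kj)),
    lhn = div(cn, ki * kj),
    aa = sum(vapply(common, function(z) 1 / log(deg(z)), 1)),
    ra = sum(vapply(common, function(z) 1 / deg(z), 1)),
    pa = ki * kj,
    lp = {
      A <- as.matrix(igraph::as_adjacency_matrix(g))
      i <- match(u, nm); j <- match(v, nm)
      A2 <- A %*% A
      (A2 + beta * A2 %*% A)[i, j]
    },
    stop("no oracle for method ", method)
  )
}

oracle_assortativity <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  k <- igraph::degree(g)
  stats::cor(c(k[el[, 1]], k[el[, 2]]), c(k[el[, 2]], k[el[, 1]]))
}

edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
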