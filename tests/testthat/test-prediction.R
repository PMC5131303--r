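# Build an edge_split by hand with a chosen probe set, for deterministic
# partition tests.
manual_split <- function(g, probe_pairs, fraction = 0.1) {
  g <- igraph::as_undirected(g)
  eids <- igraph::get_edge_ids(g, as.vector(t(probe_pairs)))
  stopifnot(all(eids > 0))
  probe <- cbind(pmin(probe_pairs[, 1], probe_pairs[, 2]),
                 pmax(probe_pairs[, 1], probe_pairs[, 2]))
  colnames(probe) <- c("node_i", "node_j")
  structure(list(graph = g, training = igraph::delete_edges(g, eids),
                 probe = probe, probe_fraction = fraction, seed = NULL),
            class = "edge_split")
}

test_that("splits have the documented sizes and are seed-reproducible", {
  g <- karate_club()
  sp <- split_edges(g, 0.1, seed = 1)
  expect_equal(nrow(sp$probe), 8)
  expect_equal(igraph::ecount(sp$training), 70)

  sp2 <- split_edges(g, 0.1, seed = 1)
  expect_identical(sp$probe, sp2$probe)
  sp3 <- split_edges(g, 0.1, seed = 2)
  expect_false(identical(sp$probe, sp3$probe))

  g10 <- random_test_graph(10, 0.25, seed = 100)
  m <- igraph::ecount(g10)
  sp4 <- split_edges(g10, 0.2, seed = 1)
  expect_equal(nrow(sp4$probe), floor(0.2 * m + 0.5))

  expect_error(split_edges(g, 0), "probe_fraction")
  expect_error(split_edges(g, 1.5), "probe_fraction")
})

test_that("training and probe sets partition the edge set", {
  g <- karate_club()
  sp <- split_edges(g, 0.2, seed = 9)
  el <- igraph::as_edgelist(g)
  et <- igraph::as_edgelist(sp$training)
  all_keys <- edge_key(el[, 1], el[, 2])
  t_keys <- edge_key(et[, 1], et[, 2])
  p_keys <- edge_key(sp$probe[, 1], sp$probe[, 2])
  expect_length(intersect(t_keys, p_keys), 0)
  expect_setequal(c(t_keys, p_keys), all_keys)
})

test_that("probe partition classifies by common neighbours in the training graph", {
  sp <- manual_split(g_triangle(), rbind(c("1", "2")))
  part <- partition_probe(sp)
  expect_equal(part$c_r, 1)
  expect_equal(nrow(part$without_cn), 0)

  sp <- manual_split(g_path4(), rbind(c("2", "3")))
  part <- partition_probe(sp)
  expect_equal(part$c_r, 0)
  expect_equal(nrow(part$with_cn), 0)
})

test_that("the training CN coefficient is the plug-in estimate", {
  sp <- manual_split(g_k4(), rbind(c("1", "2")))
  expect_equal(training_cn_coefficient(sp), 1)

  # a tree has no triangles
  tree <- g_from_edges(c(1, 2), c(1, 3), c(3, 4), c(3, 5))
  sp <- manual_split(tree, rbind(c("1", "2")))
  expect_equal(training_cn_coefficient(sp), 0)
})

test_that("plain top-L returns the best-scored candidates", {
  g <- g_path4()
  for (seed in 1:5) {
    set.seed(seed)
    pred <- predict_top_l(g, "cn", 1)
    k <- edge_key(pred$node_i, pred$node_j)
    expect_true(k %in% c("1|3", "2|4"))
  }
  pred <- predict_top_l(g, "cn", 3)
  expect_setequal(edge_key(pred$node_i, pred$node_j),
                  c("1|3", "2|4", "1|4"))
  expect_error(predict_top_l(g, "cn", 10), "exceeds")
})

test_that("predicted links never intersect the training edges", {
  g <- karate_club()
  sp <- split_edges(g, 0.1, seed = 17)
  et <- igraph::as_edgelist(sp$training)
  t_keys <- edge_key(et[, 1], et[, 2])
  for (m in c("cn", "ra", "lp", "pa")) {
    set.seed(1)
    pred <- predict_top_l(sp$training, m, 8)
    expect_equal(nrow(pred), 8)
    expect_length(intersect(edge_key(pred$node_i, pred$node_j), t_keys), 0)
  }
  pred <- predict_cnd(sp$training, 8)
  expect_equal(nrow(pred), 8)
  expect_length(intersect(edge_key(pred$node_i, pred$node_j), t_keys), 0)
})

test_that("the two-budget rule splits predictions between the pools", {
  g <- g_path4()
  set.seed(4)
  pred <- predict_cnd(g, 2, cn_prime = 0.5)
  expect_equal(attr(pred, "budget_cn"), 1)
  expect_equal(attr(pred, "budget_nocn"), 1)
  keys <- edge_key(pred$node_i, pred$node_j)
  expect_true(keys[1] %in% c("1|3", "2|4"))
  expect_equal(keys[2], "1|4")

  # cn_prime = 1 puts the whole budget on the with-CN pool
  g2 <- random_test_graph(15, 0.3, seed = 110)
  tie <- seq_len(nrow(candidate_pairs(g2)))
  pred_cnd <- predict_cnd(g2, 4, cn_prime = 1, tie_key = tie)
  pred_cn <- predict_top_l(g2, "cn", 4, tie_key = tie)
  expect_setequal(edge_key(pred_cnd$node_i, pred_cnd$node_j),
                  edge_key(pred_cn$node_i, pred_cn$node_j))
})

test_that("budget shortfall transfers to the other pool", {
  g <- g_path4()
  # only one CN=0 candidate exists, so a no-CN budget of 3 must borrow
  expect_message(pred <- predict_cnd(g, 3, cn_prime = 0), "shortfall")
  expect_equal(nrow(pred), 3)
  expect_setequal(edge_key(pred$node_i, pred$node_j),
                  c("1|3", "2|4", "1|4"))
})

test_that("selected no-CN candidates are the closest available", {
  for (seed in 1:4) {
    g <- random_test_graph(20, 0.12, seed = 120 + seed)
    sc <- cnd_scores(g)
    if (sum(sc$cn == 0) < 4) next
    set.seed(seed)
    pred <- predict_cnd(g, min(6, nrow(sc)), cn_prime = 0.5)
    sel_keys <- edge_key(pred$node_i, pred$node_j)[pred$pool == "nocn"]
    pool <- sc[sc$cn == 0, ]
    pool_keys <- edge_key(pool$node_i, pool$node_j)
    sel_d <- pool$distance[pool_keys %in% sel_keys]
    rest_d <- pool$distance[!pool_keys %in% sel_keys]
    if (length(sel_d) && length(rest_d)) {
      expect_lte(max(sel_d), min(rest_d))
    }
  }
})
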