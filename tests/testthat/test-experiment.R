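test_that("a single-realization benchmark on the 4-ring is hand-checkable", {
  # Removing one ring edge leaves a 4-path: the hidden edge's endpoints share
  # no neighbour (score 0 under CN) while both diagonals have one common
  # neighbour, so CN scores AUC = 0 and recovers nothing; the two-budget rule
  # (cn_prime = 0 on a triangle-free training graph) spends the whole budget
  # on the no-CN pool, whose single candidate is exactly the hidden edge.
  bench <- run_benchmark(list(ring = g_cycle4()), probe_fractions = 0.25,
                         realizations = 1, methods = c("cn", "cnd"),
                         master_seed = 5)
  cn <- bench[bench$method == "cn", ]
  cnd <- bench[bench$method == "cnd", ]
  expect_equal(cn$auc, 0)
  expect_equal(cn$precision, 0)
  expect_equal(cn$precision_no_cn, 0)
  expect_equal(cnd$precision, 1)
  expect_equal(cnd$precision_no_cn, 1)
  expect_equal(cnd$c_r, 0)
  expect_equal(cnd$cn_prime, 0)
})

test_that("benchmarks are a pure function of the master seed", {
  g <- random_test_graph(20, 0.3, seed = 150)
  b1 <- run_benchmark(list(g = g), probe_fractions = 0.1, realizations = 3,
                      methods = c("cn", "ra", "cnd"), master_seed = 42)
  b2 <- run_benchmark(list(g = g), probe_fractions = 0.1, realizations = 3,
                      methods = c("cn", "ra", "cnd"), master_seed = 42)
  expect_equal(b1, b2)
  b3 <- run_benchmark(list(g = g), probe_fractions = 0.1, realizations = 3,
                      methods = c("cn", "ra", "cnd"), master_seed = 43)
  expect_false(isTRUE(all.equal(b1$auc, b3$auc)))
})

test_that("adding a method never perturbs the shared splits", {
  g <- random_test_graph(20, 0.3, seed = 151)
  b1 <- run_benchmark(list(g = g), probe_fractions = 0.1, realizations = 3,
                      methods = "cn", master_seed = 7)
  b2 <- run_benchmark(list(g = g), probe_fractions = 0.1, realizations = 3,
                      methods = c("cn", "pa"), master_seed = 7)
  expect_equal(b1$c_r, b2$c_r[b2$method == "cn"])
  expect_equal(b1$auc, b2$auc[b2$method == "cn"])
  expect_equal(b1$precision, b2$precision[b2$method == "cn"])
})

test_that("invalid configurations fail before any computation", {
  g <- g_cycle4()
  expect_error(run_benchmark(list(g = g), methods = c("cn", "bogus")),
               "unknown method token")
  expect_error(run_benchmark(list(g = g), realizations = 0), "realizations")
  expect_error(run_benchmark(list(g = g), probe_fractions = c(0.1, 1.2)),
               "fractions")
  expect_error(run_benchmark(list(g), methods = "cn"), "named list")
})

test_that("on an unstructured random graph all methods hover near chance", {
  g <- generate_graph("er", n = 60, p = 0.1, seed = 160)
  bench <- run_benchmark(list(er = g), probe_fractions = 0.1,
                         realizations = 3, methods = c("cn", "cnd"),
                         master_seed = 8)
  s <- summarize_benchmark(bench)
  expect_true(all(abs(s$auc_mean - 0.5) < 0.15))
})

test_that("Jaccard and Sorensen give identical AUC and Precision per realization", {
  g <- generate_graph("ba", n = 40, m = 2, seed = 161)
  bench <- run_benchmark(list(ba = g), probe_fractions = 0.1,
                         realizations = 5,
                         methods = c("jaccard", "sorensen"), master_seed = 3)
  j <- bench[bench$method == "jaccard", ]
  s <- bench[bench$method == "sorensen", ]
  expect_equal(j$auc, s$auc)
  expect_equal(j$precision, s$precision)
})

test_that("summaries aggregate means and sds and format like the tables", {
  g <- random_test_graph(20, 0.3, seed = 152)
  bench <- run_benchmark(list(g = g), probe_fractions = 0.1, realizations = 4,
                         methods = "cn", master_seed = 2)
  s <- summarize_benchmark(bench)
  expect_equal(nrow(s), 1)
  expect_equal(s$auc_mean, mean(bench$auc))
  expect_equal(s$auc_sd, sd(bench$auc))
  expect_equal(s$n_realizations, 4)

  expect_equal(format_summary_cell(0.721, 0.0078), "0.721(78)")
  expect_equal(format_summary_cell(0.05, 0.0224), "0.050(224)")

  f <- withr::local_tempfile(fileext = ".csv")
  write_summary(s, f)
  s2 <- read.csv(f)
  expect_equal(s2$auc_mean, s$auc_mean)
  expect_equal(nrow(s2), nrow(s))
})

test_that("diagnostics relate the estimator and accuracy to the CN coefficient", {
  graphs <- list(
    ws = generate_graph("ws", n = 60, k = 6, p = 0.1, seed = 1),
    ba = generate_graph("ba", n = 60, m = 2, seed = 2),
    er = generate_graph("er", n = 60, p = 0.06, seed = 3))
  bench <- run_benchmark(graphs, probe_fractions = 0.1, realizations = 3,
                         methods = c("cn", "cnd"), master_seed = 4)
  rep <- diagnostics_report(bench)
  expect_equal(nrow(rep$estimator), 1)
  expect_gte(rep$estimator$rmse, 0)
  expect_lt(rep$estimator$rmse, 0.2)
  expect_true(all(c("method", "metric", "cc") %in% names(rep$metric_vs_cn)))

  one <- run_benchmark(list(ws = graphs$ws), probe_fractions = 0.1,
                       realizations = 2, methods = "cn", master_seed = 4)
  expect_error(diagnostics_report(one), "at least two networks")
})
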