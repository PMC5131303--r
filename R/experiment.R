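# Benchmark harness: repeated seeded splits, per-method evaluation and
# mean +/- sd aggregation over realizations.

#' Run a link-prediction benchmark over repeated random splits
#'
#' For each network, probe fraction and realization, hides a random probe
#' set, evaluates every requested method on the same split (splits and
#' tie-break permutations are derived from `master_seed` and shared across
#' methods, so comparisons are paired), and collects AUC, Precision and
#' without-CN Precision per realization. The whole run is a pure function of
#' its inputs and `master_seed`.
#'
#' @param graphs A named list of undirected simple `igraph` graphs (a single
#'   graph is accepted and named `"network"`).
#' @param probe_fractions Fractions of edges to hide (default `c(0.1, 0.2)`).
#' @param realizations Number of random splits per condition (default 20).
#' @param methods Similarity method tokens (default: all twelve).
#' @param master_seed Integer master seed (default 1).
#' @param auc_mode `"exact"` or `"sampled"`.
#' @param tie_break `"random"` or `"deterministic"`.
#' @param beta Local-path damping weight.
#' @return A `data.frame` of class `benchmark_result`, one row per (network,
#'   fraction, realization, method), with columns `auc`, `precision`,
#'   `precision_no_cn`, `relevant`, `c_r`, `cn_prime`, `n_probe`. The CN
#'   coefficient of each original network is attached as attribute
#'   `network_cn`.
#' @examples
#' bench <- run_benchmark(list(karate = karate_club()),
#'                        probe_fractions = 0.1, realizations = 2,
#'                        methods = c("cn", "cnd"), master_seed = 1)
#' summarize_benchmark(bench)
#' @export
run_benchmark <- function(graphs, probe_fractions = c(0.1, 0.2),
                          realizations = 20,
                          methods = similarity_methods(),
                          master_seed = 1,
                          auc_mode = c("exact", "sampled"),
                          tie_break = c("random", "deterministic"),
                          beta = 0.01) {
  if (igraph::is_igraph(graphs)) graphs <- list(network = graphs)
  if (is.null(names(graphs)) || any(names(graphs) == "")) {
    stop("graphs must be a named list", call. = FALSE)
  }
  auc_mode <- match.arg(auc_mode)
  tie_break <- match.arg(tie_break)
  bad <- setdiff(methods, similarity_methods())
  if (length(bad)) {
    stop("unknown method token(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (realizations < 1) stop("realizations must be >= 1", call. = FALSE)
  if (any(probe_fractions <= 0 | probe_fractions >= 1)) {
    stop("probe fractions must be in (0, 1)", call. = FALSE)
  }

  rows <- list()
  for (net in names(graphs)) {
    g <- as_cnd_graph(graphs[[net]])
    for (f in probe_fractions) {
      for (r in seq_len(realizations)) {
        split_seed <- hash_seed(master_seed, net, f, r, "split")
        split <- split_edges(g, f, seed = split_seed)
        n_cand <- length(candidate_index(split$training)$i)
        tie_key <- switch(tie_break,
          random = with_seed(hash_seed(master_seed, net, f, r, "tie"),
                             stats::runif(n_cand)),
          deterministic = seq_len(n_cand))
        for (meth in methods) {
          row <- evaluate_method(split, meth, beta = beta,
                                 auc_mode = auc_mode, tie_key = tie_key)
          rows[[length(rows) + 1L]] <- cbind(
            data.frame(network = net, fraction = f, realization = r,
                       stringsAsFactors = FALSE),
            row)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "network_cn") <- vapply(graphs, function(g) {
    cn_coefficient(as_cnd_graph(g))
  }, numeric(1))
  class(out) <- c("benchmark_result", "data.frame")
  out
}

#' Aggregate a benchmark into per-condition means and standard deviations
#'
#' @param bench A `benchmark_result` from [run_benchmark()].
#' @return A `data.frame` with one row per (network, fraction, method):
#'   mean and sample standard deviation (ddof = 1) of AUC, Precision and
#'   without-CN Precision over realizations (realizations where without-CN
#'   Precision is undefined are dropped from its average), plus mean `c_r`
#'   and `cn_prime` and the realization count.
#' @export
summarize_benchmark <- function(bench) {
  stopifnot(inherits(bench, "benchmark_result"))
  groups <- unique(bench[, c("network", "fraction", "method")])
  res <- lapply(seq_len(nrow(groups)), function(i) {
    sel <- bench$network == groups$network[i] &
      bench$fraction == groups$fraction[i] &
      bench$method == groups$method[i]
    b <- bench[sel, ]
    data.frame(
      network = groups$network[i],
      fraction = groups$fraction[i],
      method = groups$method[i],
      auc_mean = mean(b$auc), auc_sd = stats::sd(b$auc),
      precision_mean = mean(b$precision), precision_sd = stats::sd(b$precision),
      precision_no_cn_mean = mean(b$precision_no_cn, na.rm = TRUE),
      precision_no_cn_sd = stats::sd(b$precision_no_cn, na.rm = TRUE),
      c_r_mean = mean(b$c_r),
      cn_prime_mean = mean(b$cn_prime),
      n_realizations = nrow(b),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Format a mean and standard deviation in compact table style
#'
#' Renders `0.721` with sd `0.0078` as `"0.721(78)"`: the mean to three
#' decimals with the standard deviation in units of 1e-4 in brackets.
#'
#' @param mean,sd Numeric scalars (vectorised).
#' @return Character vector.
#' @examples
#' format_summary_cell(0.721, 0.0078) # "0.721(78)"
#' @export
format_summary_cell <- function(mean, sd) {
  sprintf("%.3f(%d)", mean, as.integer(round(sd * 1e4)))
}

#' Write a benchmark summary to a tidy CSV file
#'
#' @param summary A summary `data.frame` from [summarize_benchmark()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path) {
  if (nrow(summary) == 0) stop("empty summary", call. = FALSE)
  utils::write.csv(summary, path, row.names = FALSE)
  invisible(path)
}

#' Estimator and correlation diagnostics across benchmark networks
#'
#' Computes, per probe fraction, the RMSE and Pearson correlation between the
#' mean training-graph CN coefficient (the plug-in estimate) and the mean
#' realised with-CN probe fraction `c_r` across networks, and the per-method
#' Pearson correlation of each accuracy metric with the networks' CN
#' coefficient.
#'
#' @param bench A `benchmark_result` covering at least two networks.
#' @return A list with `estimator` (data.frame: fraction, rmse, cc) and
#'   `metric_vs_cn` (data.frame: fraction, method, metric, cc).
#' @export
diagnostics_report <- function(bench) {
  stopifnot(inherits(bench, "benchmark_result"))
  s <- summarize_benchmark(bench)
  if (length(unique(s$network)) < 2) {
    stop("diagnostics need at least two networks", call. = FALSE)
  }
  network_cn <- attr(bench, "network_cn")

  est <- lapply(unique(s$fraction), function(f) {
    # c_r and cn_prime are split-level quantities, identical across methods
    sf <- s[s$fraction == f & s$method == s$method[1], ]
    d <- estimator_diagnostics(sf$cn_prime_mean, sf$c_r_mean)
    data.frame(fraction = f, rmse = d$rmse, cc = d$cc)
  })

  combos <- expand.grid(fraction = unique(s$fraction),
                        method = unique(s$method),
                        metric = c("auc_mean", "precision_mean"),
                        stringsAsFactors = FALSE)
  met <- lapply(seq_len(nrow(combos)), function(i) {
    sf <- s[s$fraction == combos$fraction[i] & s$method == combos$method[i], ]
    x <- network_cn[sf$network]
    y <- sf[[combos$metric[i]]]
    cc <- if (stats::sd(x) > 0 && stats::sd(y) > 0) stats::cor(x, y) else NA_real_
    data.frame(fraction = combos$fraction[i], method = combos$method[i],
               metric = sub("_mean$", "", combos$metric[i]), cc = cc,
               stringsAsFactors = FALSE)
  })
  list(estimator = do.call(rbind, est), metric_vs_cn = do.call(rbind, met))
}
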