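# AUC and Precision metrics for link prediction on a train/probe split.

#' Exact AUC from probe and non-existent link scores
#'
#' Probability that a randomly chosen probe link outscores a randomly chosen
#' non-existent link, with half credit for ties: the Mann-Whitney statistic
#' `(n' + 0.5 n'') / n` computed exhaustively over all pairs of comparisons
#' via midranks rather than by sampling.
#'
#' @param probe_scores Scores of the probe (hidden true) links.
#' @param nonexistent_scores Scores of true non-links of the original graph.
#' @return A value in `[0, 1]`.
#' @examples
#' auc_exact(c(2, 1), c(1, 0)) # 0.875
#' @export
auc_exact <- function(probe_scores, nonexistent_scores) {
  n1 <- length(probe_scores)
  n2 <- length(nonexistent_scores)
  if (n1 == 0 || n2 == 0) {
    stop("both score sets must be non-empty", call. = FALSE)
  }
  r <- rank(c(probe_scores, nonexistent_scores))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Sampled AUC by Monte-Carlo comparisons
#'
#' Draws `n` independent (probe, non-existent) score comparisons and returns
#' `(n' + 0.5 n'') / n`; converges to [auc_exact()] as `n` grows.
#'
#' @inheritParams auc_exact
#' @param n Number of comparisons.
#' @param seed Optional integer seed.
#' @return A value in `[0, 1]`.
#' @export
auc_sampled <- function(probe_scores, nonexistent_scores, n, seed = NULL) {
  if (length(probe_scores) == 0 || length(nonexistent_scores) == 0) {
    stop("both score sets must be non-empty", call. = FALSE)
  }
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  with_seed(seed, {
    a <- probe_scores[sample.int(length(probe_scores), n, replace = TRUE)]
    b <- nonexistent_scores[sample.int(length(nonexistent_scores), n,
                                       replace = TRUE)]
    mean((a > b) + 0.5 * (a == b))
  })
}

#' Top-L Precision of a prediction against the probe set
#'
#' Fraction of the `L` predicted links that are true probe links, with `L`
#' fixed to the probe-set size (the standard protocol: predict exactly as
#' many links as were hidden).
#'
#' @param pred A `link_prediction` (or data.frame with `node_i`, `node_j`).
#' @param probe Two-column matrix of probe edges, e.g. `split$probe`.
#' @return A list with `precision` (= `relevant / L`) and `relevant` (the hit
#'   count L_r).
#' @export
precision_top_l <- function(pred, probe) {
  L <- nrow(pred)
  if (L != nrow(probe)) {
    stop("prediction size (", L, ") must equal probe size (", nrow(probe),
         ")", call. = FALSE)
  }
  hits <- pair_key(pred$node_i, pred$node_j) %in%
    pair_key(probe[, 1], probe[, 2])
  list(precision = mean(hits), relevant = sum(hits))
}

#' Precision on probe links without common neighbors
#'
#' Fraction of the without-CN probe links (endpoints sharing no neighbour in
#' the training graph) that the prediction recovered. This is the part of the
#' probe set that plain common-neighbour indices cannot reach at all.
#'
#' @param pred A `link_prediction`.
#' @param partition A `probe_partition` from [partition_probe()] on the same
#'   split.
#' @return Proportion recovered, or `NA` when the split produced no
#'   without-CN probe link (undefined, never silently 0).
#' @export
precision_no_cn <- function(pred, partition) {
  stopifnot(inherits(partition, "probe_partition"))
  ep2 <- partition$without_cn
  if (nrow(ep2) == 0) return(NA_real_)
  hits <- pair_key(ep2[, 1], ep2[, 2]) %in% pair_key(pred$node_i, pred$node_j)
  mean(hits)
}

#' Evaluate one method on one split
#'
#' Convenience wrapper running the full per-realization protocol for a single
#' method: score all candidates of the training graph, compute AUC (probe vs
#' true non-links of the original graph), predict top-L links and compute
#' Precision and without-CN Precision.
#'
#' @param split An `edge_split`.
#' @param method A similarity method token (see [score_pairs()]).
#' @param beta Local-path damping weight.
#' @param auc_mode `"exact"` (default) or `"sampled"`.
#' @param auc_n Number of comparisons when `auc_mode = "sampled"`; default
#'   100 times the number of scored links.
#' @param tie_break,tie_key Passed to the predictor.
#' @return A one-row `data.frame`: `method`, `auc`, `precision`,
#'   `precision_no_cn`, `relevant`, `c_r`, `cn_prime`, `n_probe`.
#' @export
evaluate_method <- function(split, method, beta = 0.01,
                            auc_mode = c("exact", "sampled"), auc_n = NULL,
                            tie_break = c("random", "deterministic"),
                            tie_key = NULL) {
  stopifnot(inherits(split, "edge_split"))
  auc_mode <- match.arg(auc_mode)
  tie_break <- match.arg(tie_break)
  gt <- split$training
  L <- nrow(split$probe)

  sc <- score_pairs(gt, method)
  key <- pair_key(sc$node_i, sc$node_j)
  probe_key <- pair_key(split$probe[, 1], split$probe[, 2])
  is_probe <- key %in% probe_key
  # non-existent links are the non-links of the original graph: candidates of
  # the training graph minus the hidden probe links
  pos <- sc$score[is_probe]
  neg <- sc$score[!is_probe]
  auc <- if (auc_mode == "exact") {
    auc_exact(pos, neg)
  } else {
    if (is.null(auc_n)) auc_n <- 100 * length(sc$score)
    auc_sampled(pos, neg, auc_n)
  }

  part <- partition_probe(split)
  cn_prime <- training_cn_coefficient(split)
  pred <- if (method == "cnd") {
    predict_cnd(gt, L, cn_prime = cn_prime, tie_break = tie_break,
                tie_key = tie_key)
  } else {
    predict_top_l(gt, method, L, beta = beta, tie_break = tie_break,
                  tie_key = tie_key)
  }
  prec <- precision_top_l(pred, split$probe)
  data.frame(method = method,
             auc = auc,
             precision = prec$precision,
             precision_no_cn = precision_no_cn(pred, part),
             relevant = prec$relevant,
             c_r = part$c_r,
             cn_prime = cn_prime,
             n_probe = L,
             stringsAsFactors = FALSE)
}
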