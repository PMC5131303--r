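# Internal helpers shared across modules.

#' @importFrom stats runif sd cor
#' @importFrom utils head write.csv read.csv
NULL

# Round half away from zero. Used for probe-set sizes and prediction budgets;
# base round() is round-half-even, which would make 10%/20% tables depend on
# parity of m.
round_half_up <- function(x) trunc(x + 0.5 * sign(x))

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL means "use the current stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic 31-bit hash of a character key, for deriving child seeds from a
# master seed. Polynomial rolling hash mod (2^31 - 1); stays inside R's
# integer range by doing the arithmetic in doubles.
hash_seed <- function(master_seed, ...) {
  key <- paste(c(master_seed, ...), collapse = "\r")
  p <- 2147483647
  h <- 0
  for (cp in utf8ToInt(key)) h <- (h * 131 + cp) %% p
  as.integer(h)
}

# Canonical string key for an unordered node pair; used to intersect pair sets.
pair_key <- function(i, j) {
  paste(pmin(i, j), pmax(i, j), sep = "\r")
}

# Validate and normalise a graph argument: must be an igraph object; vertices
# get character names if absent so results are stable under reindexing.
as_cnd_graph <- function(g) {
  if (!igraph::is_igraph(g)) stop("`g` must be an igraph object", call. = FALSE)
  if (is.null(igraph::V(g)$name)) {
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  }
  g
}

# Canonicalise an arbitrary igraph to the undirected simple form every
# operation assumes. Directed or multi input is collapsed with a warning.
ensure_simple_undirected <- function(g, warn = TRUE) {
  changed <- FALSE
  if (igraph::is_directed(g)) {
    g <- igraph::as_undirected(g, mode = "collapse")
    changed <- TRUE
  }
  if (igraph::any_multiple(g) || any(igraph::which_loop(g))) {
    g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
    changed <- TRUE
  }
  if (changed && warn) {
    warning("input graph canonicalised to undirected simple form", call. = FALSE)
  }
  g
}
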