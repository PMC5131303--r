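#' Read an undirected simple graph from a whitespace-separated edge list
#'
#' Each non-blank, non-comment line names one edge as two (or more; extra
#' tokens are ignored) whitespace-separated node labels. Lines starting with
#' `#` are comments. Duplicate lines and reversed duplicates collapse to a
#' single undirected edge; self-loops are rejected because every method here
#' assumes a simple graph.
#'
#' @param path Path to the edge-list file (UTF-8).
#' @return An undirected simple `igraph` graph with character vertex names.
#' @examples
#' f <- tempfile()
#' writeLines(c("1 2", "2 3", "3 1"), f)
#' g <- read_edge_list(f)
#' igraph::ecount(g) # 3
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  tokens <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(vapply(tokens, length, 1L) < 2L)
  if (length(bad)) {
    stop("malformed edge-list line ", idx[bad[1]], ": ",
         lines[idx[bad[1]]], call. = FALSE)
  }
  from <- vapply(tokens, `[`, "", 1L)
  to <- vapply(tokens, `[`, "", 2L)
  loop <- which(from == to)
  if (length(loop)) {
    stop("self-loop on line ", idx[loop[1]], ": ", lines[idx[loop[1]]],
         call. = FALSE)
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  ensure_simple_undirected(g, warn = FALSE)
}

#' Write a graph as a whitespace-separated edge list
#'
#' One edge per line, labels separated by a single space. Inverse of
#' [read_edge_list()] up to node/edge set equality.
#'
#' @param g An undirected `igraph` graph.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  g <- as_cnd_graph(g)
  el <- igraph::as_edgelist(g)
  writeLines(paste(el[, 1], el[, 2]), path)
  invisible(path)
}

#' Read a graph from a GML file
#'
#' Reads the GML dialect used by the classical network benchmark archives
#' (Zachary karate, dolphins, political books, ...). Directionality is
#' discarded and multi-edges are collapsed, with a warning, since all methods
#' in this package operate on undirected simple graphs.
#'
#' @param path Path to a GML file.
#' @return An undirected simple `igraph` graph. Vertex names come from the GML
#'   `label` attribute when present, otherwise from the numeric `id`.
#' @export
read_gml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  g <- tryCatch(
    igraph::read_graph(path, format = "gml"),
    error = function(e) stop("cannot parse GML file ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (is.null(igraph::V(g)$name)) {
    id <- igraph::vertex_attr(g, "id")
    igraph::V(g)$name <- if (!is.null(id)) as.character(id) else
      as.character(seq_len(igraph::vcount(g)))
  }
  ensure_simple_undirected(g)
}

#' Zachary's karate club network
#'
#' The 34-node, 78-edge social network of a university karate club, the
#' canonical small benchmark for link prediction and community structure. The
#' copy bundled with the package is read from a plain-text edge list under
#' `inst/extdata`.
#'
#' @return An undirected simple `igraph` graph with 34 vertices and 78 edges.
#' @examples
#' g <- karate_club()
#' igraph::vcount(g)
#' @export
karate_club <- function() {
  path <- system.file("extdata", "karate.edgelist", package = "cndlink",
                      mustWork = TRUE)
  read_edge_list(path)
}
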