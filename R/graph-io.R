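#' Read an undirected simple graph from an edge-list file
#'
#' Parses a plain-text edge list: one edge per line, two whitespace- or
#' comma-separated node tokens, `#` starting a comment.  Node ids in the file
#' are arbitrary tokens (the conventional on-disk ids are 0-based integers,
#' see [write_edge_list()]); they are renumbered to igraph's 1..N in order of
#' first appearance.  Duplicate edges are collapsed with a warning;
#' self-loops are an error.
#'
#' @param source path to a file, or a connection, or a character vector of
#'   lines.
#' @param require_connected error if the graph is not connected (fixation is
#'   ill-defined on disconnected graphs).  Default `TRUE`.
#' @return an [igraph][igraph::igraph-package] graph with vertex attribute
#'   `label` holding the original file tokens.
#' @seealso [write_edge_list()]
#' @export
read_edge_list <- function(source, require_connected = TRUE) {
  lines <- if (is.character(source) && length(source) > 1) {
    source
  } else if (is.character(source) && !file.exists(source)) {
    strsplit(source, "\n", fixed = TRUE)[[1]]
  } else {
    readLines(source)
  }
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    stop("empty edge list: no edges found", call. = FALSE)
  }
  toks <- strsplit(lines, "[,[:space:]]+")
  bad <- which(lengths(toks) != 2L)
  if (length(bad)) {
    stop("line ", bad[1L], ": expected two node tokens, got ",
         lengths(toks)[bad[1L]], call. = FALSE)
  }
  a <- vapply(toks, `[`, character(1), 1L)
  b <- vapply(toks, `[`, character(1), 2L)
  loops <- which(a == b)
  if (length(loops)) {
    stop("line ", loops[1L], ": self-loop '", a[loops[1L]], " ", b[loops[1L]],
         "' not allowed", call. = FALSE)
  }
  labels <- unique(c(rbind(a, b)))          # first-appearance order
  ia <- match(a, labels)
  ib <- match(b, labels)
  key <- paste(pmin(ia, ib), pmax(ia, ib))
  if (anyDuplicated(key)) {
    warning("collapsed ", sum(duplicated(key)), " duplicate edge(s)",
            call. = FALSE)
    keep <- !duplicated(key)
    ia <- ia[keep]; ib <- ib[keep]
  }
  g <- igraph::make_empty_graph(n = length(labels), directed = FALSE)
  g <- igraph::add_edges(g, rbind(ia, ib))
  igraph::V(g)$label <- labels
  if (require_connected && !igraph::is_connected(g)) {
    stop("graph is not connected (", igraph::count_components(g),
         " components)", call. = FALSE)
  }
  g
}

#' Write a graph as a canonical edge-list file
#'
#' One edge per line, smaller node id first, lines sorted; a `#` header
#' records the node and edge counts.  On disk node ids are 0-based (the
#' format is language-neutral); [read_edge_list()] maps them back to 1..N.
#'
#' @param graph an igraph graph (undirected, simple).
#' @param sink file path or connection.
#' @return `invisible(NULL)`.
#' @export
write_edge_list <- function(graph, sink) {
  stopifnot(igraph::is_igraph(graph))
  el <- igraph::as_edgelist(graph, names = FALSE)
  lo <- pmin(el[, 1], el[, 2]) - 1L
  hi <- pmax(el[, 1], el[, 2]) - 1L
  ord <- order(lo, hi)
  out <- c(
    sprintf("# nodes: %d  edges: %d", igraph::vcount(graph), nrow(el)),
    sprintf("%d %d", lo[ord], hi[ord])
  )
  writeLines(out, sink)
  invisible(NULL)
}
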