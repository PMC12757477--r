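# PPI network assembly over the pipeline's significant players, and hub
# ranking by node degree.

#' Build the annotated protein-protein interaction network
#'
#' Induced subgraph of a PPI edge list on the union of the supplied node
#' sets (DEPs, parents of differentially phosphorylated peptides, kinases,
#' phosphatases, TFs, ...). Edges are undirected and unweighted; duplicate
#' and reversed edges collapse to one, self-loops are removed. Isolated
#' nodes are retained with degree 0; roles may overlap.
#'
#' @param ppi_edges data.frame whose first two columns are interactor ids;
#'   an optional numeric \code{score} column can be thresholded with
#'   \code{min_score} (scores are never weighted into degree).
#' @param node_sets named list of character vectors, one per role.
#' @param min_score drop edges with \code{score < min_score} (ignored if no
#'   score column).
#' @return an \code{AnnotatedNetwork} list: \code{nodes} (node, degree,
#'   roles), \code{edges} (canonicalized a < b), and \code{graph} (igraph).
#' @examples
#' edges <- data.frame(a = c("a", "a", "a", "b"), b = c("b", "c", "d", "a"))
#' net <- buildNetwork(edges, list(seed = c("a", "b", "c", "d")))
#' net$nodes
#' @export
buildNetwork <- function(ppi_edges, node_sets, min_score = NULL) {
  if (!nrow(ppi_edges)) stop("empty PPI edge list")
  nodes <- sort(unique(unlist(node_sets, use.names = FALSE)))
  if (!length(nodes)) stop("empty node-set union")
  a <- as.character(ppi_edges[[1L]])
  b <- as.character(ppi_edges[[2L]])
  if (!is.null(min_score) && "score" %in% names(ppi_edges)) {
    keep <- !is.na(ppi_edges$score) & ppi_edges$score >= min_score
    a <- a[keep]; b <- b[keep]
  }
  keep <- a %in% nodes & b %in% nodes & a != b
  a <- a[keep]; b <- b[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  edges <- unique(data.frame(a = lo, b = hi, stringsAsFactors = FALSE))
  edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  rownames(edges) <- NULL
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  deg <- igraph::degree(g)
  roles <- vapply(nodes, function(nd) {
    paste(sort(names(node_sets)[vapply(node_sets, function(s) nd %in% s,
                                       logical(1L))]), collapse = ",")
  }, character(1L))
  net <- list(nodes = data.frame(node = nodes, degree = as.integer(deg[nodes]),
                                 roles = unname(roles),
                                 stringsAsFactors = FALSE),
              edges = edges, graph = g)
  class(net) <- "AnnotatedNetwork"
  net
}

#' @export
print.AnnotatedNetwork <- function(x, ...) {
  cat(sprintf("AnnotatedNetwork: %d nodes, %d edges; max degree %d (%s)\n",
              nrow(x$nodes), nrow(x$edges), max(x$nodes$degree),
              paste(x$nodes$node[x$nodes$degree == max(x$nodes$degree)],
                    collapse = ", ")))
  invisible(x)
}

#' Rank network hubs by degree
#'
#' @param net an \code{AnnotatedNetwork} from [buildNetwork].
#' @param top_n number of nodes to return; a value beyond the node count
#'   returns the full ranking.
#' @return data.frame (node, degree, roles) in descending degree order, ties
#'   broken lexicographically by node id.
#' @export
rankHubs <- function(net, top_n = 10L) {
  nodes <- net$nodes
  if (!nrow(nodes)) stop("empty network")
  ord <- order(-nodes$degree, nodes$node)
  out <- nodes[ord, , drop = FALSE][seq_len(min(top_n, nrow(nodes))), ,
                                    drop = FALSE]
  rownames(out) <- NULL
  out
}
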