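# Hypergeometric overrepresentation analysis, bubble-plot term selection,
# binary TF-target matrix and its two-way hierarchical clustering.

#' Hypergeometric overrepresentation analysis
#'
#' For each gene set with at least one query hit, the upper-tail
#' hypergeometric probability P[X >= k] of drawing k or more set members in
#' a query of size n from a universe of size N containing K set members.
#' BH adjustment across the tested sets; output sorted by adjusted p.
#'
#' Query genes outside the universe are dropped (count reported); set
#' members outside the universe do not count toward K.
#'
#' @param query character vector of query gene ids.
#' @param collection named list of gene sets (see [readGmt]).
#' @param universe character vector of measurable gene ids.
#' @return data.frame (set_name, source_db, k, K, n, N, p_raw, p_adj,
#'   overlap_genes [list-column]) with attribute \code{n_query_dropped}.
#' @examples
#' ora(query = letters[1:5], collection = list(s = letters[1:5]),
#'     universe = letters[1:10])$p_raw   # 1 / choose(10, 5)
#' @export
ora <- function(query, collection, universe) {
  universe <- unique(as.character(universe))
  query0 <- unique(as.character(query))
  query <- intersect(query0, universe)
  nDropped <- length(query0) - length(query)
  if (nDropped)
    message(nDropped, " query gene(s) outside the universe dropped")
  if (!length(query)) stop("empty query after universe filtering")
  if (!length(collection)) stop("empty gene-set collection")
  src <- attr(collection, "source_db")
  if (is.null(src)) src <- rep("unknown", length(collection))
  N <- length(universe)
  n <- length(query)
  rows <- lapply(seq_along(collection), function(i) {
    members <- intersect(unique(collection[[i]]), universe)
    hits <- intersect(members, query)
    k <- length(hits)
    if (k == 0L) return(NULL)
    K <- length(members)
    data.frame(set_name = names(collection)[i], source_db = src[i],
               k = k, K = K, n = n, N = N,
               p_raw = stats::phyper(k - 1L, K, N - K, n,
                                     lower.tail = FALSE),
               overlap_genes = I(list(sort(hits))),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows))
    return(structure(data.frame(set_name = character(), source_db = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p_raw = numeric(), p_adj = numeric(),
                      stringsAsFactors = FALSE),
                     n_query_dropped = nDropped))
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_raw, method = "BH")
  out <- out[order(out$p_adj, out$p_raw, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_query_dropped") <- nDropped
  out
}

#' Select terms for a bubble plot across source databases
#'
#' Published selection rules: (i) sort terms by adjusted p; (ii) when the
#' same term name occurs in several source databases, keep the occurrence
#' with the smallest adjusted p; (iii) when related terms cover essentially
#' the same genes (overlap-member Jaccard at or above
#' \code{jaccard_collapse}), keep only the most general one (largest K; ties
#' broken by smaller adjusted p, then name). An explicit, user-supplied
#' exclusion list drops terms irrelevant to the tissue under study — this is
#' never inferred automatically.
#'
#' @param rows one [ora] result or a list of them (e.g. one per source
#'   database); rows must carry \code{overlap_genes}.
#' @param jaccard_collapse Jaccard threshold for rule (iii), default 0.75.
#' @param exclude character vector of term names to drop.
#' @return the selected rows, sorted by adjusted p.
#' @export
selectBubbleTerms <- function(rows, jaccard_collapse = 0.75,
                              exclude = character()) {
  if (is.data.frame(rows)) rows <- list(rows)
  all <- do.call(rbind, rows)
  if (!nrow(all)) return(all)
  all <- all[!(all$set_name %in% exclude), , drop = FALSE]
  # rule i + ii: best adjusted p per term name
  all <- all[order(all$p_adj, all$p_raw, all$set_name, all$source_db), ,
             drop = FALSE]
  all <- all[!duplicated(all$set_name), , drop = FALSE]
  # rule iii: collapse near-identical member sets, keep the most general
  keepOrder <- order(-all$K, all$p_adj, all$set_name)
  cand <- all[keepOrder, , drop = FALSE]
  kept <- logical(nrow(cand))
  keptGenes <- list()
  for (i in seq_len(nrow(cand))) {
    g <- cand$overlap_genes[[i]]
    dup <- any(vapply(keptGenes, function(h) {
      length(intersect(g, h)) / length(union(g, h)) >= jaccard_collapse
    }, logical(1L)))
    if (!dup) {
      kept[i] <- TRUE
      keptGenes[[length(keptGenes) + 1L]] <- g
    }
  }
  out <- cand[kept, , drop = FALSE]
  out <- out[order(out$p_adj, out$p_raw, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Binary TF-target incidence matrix over DE genes
#'
#' Cell (i, j) is 1 iff gene i is an annotated target of TF j. TFs are
#' restricted to an expressed-TF filter (e.g. ids detected in the MS or
#' RNA-Seq data); genes are restricted to the DE genes having at least one
#' retained regulator; TFs with no retained target are dropped (reported).
#'
#' @param degs character vector of DE gene ids (matrix rows).
#' @param tf_edges data.frame whose first two columns are TF and target ids.
#' @param expressed_filter character vector of expressed feature ids used to
#'   filter TFs; \code{NULL} keeps all TFs.
#' @return binary integer matrix, rows = genes, columns = TFs (both sorted
#'   lexicographically), with attribute \code{dropped_tfs}.
#' @examples
#' edges <- data.frame(tf = c("tf1", "tf1", "tf2"),
#'                     target = c("g1", "g2", "g2"))
#' buildTfMatrix(c("g1", "g2", "g3"), edges)
#' @export
buildTfMatrix <- function(degs, tf_edges, expressed_filter = NULL) {
  if (!nrow(tf_edges)) stop("empty TF-target edge list")
  tf <- as.character(tf_edges[[1L]])
  target <- as.character(tf_edges[[2L]])
  if (!is.null(expressed_filter)) {
    keep <- tf %in% expressed_filter
    tf <- tf[keep]; target <- target[keep]
  }
  keep <- target %in% degs
  tf <- tf[keep]; target <- target[keep]
  allTfs <- sort(unique(as.character(tf_edges[[1L]])))
  tfs <- sort(unique(tf))
  droppedTfs <- setdiff(
    if (is.null(expressed_filter)) allTfs
    else intersect(allTfs, expressed_filter), tfs)
  if (!length(tfs))
    stop("no TF survives the expression/target filters")
  if (length(droppedTfs))
    message(length(droppedTfs), " TF(s) dropped (no retained target)")
  genes <- sort(unique(target))
  m <- matrix(0L, length(genes), length(tfs),
              dimnames = list(genes, tfs))
  m[cbind(match(target, genes), match(tf, tfs))] <- 1L
  attr(m, "dropped_tfs") <- droppedTfs
  m
}

# 1 - Pearson distance between the rows of m; constant rows get maximal
# distance (2) to everything else and 0 to themselves
.pearson_dist <- function(m) {
  v <- apply(m, 1L, stats::var)
  constant <- v == 0
  if (any(constant))
    message(sum(constant), " constant row(s)/column(s): Pearson undefined, ",
            "assigned maximal distance")
  cc <- suppressWarnings(stats::cor(t(m)))
  d <- 1 - cc
  d[is.na(d)] <- 2
  diag(d) <- 0
  stats::as.dist(d)
}

#' Two-way hierarchical clustering of a binary TF-target matrix
#'
#' Average-linkage hierarchical clustering with 1 - Pearson correlation as
#' the distance, applied to genes (rows) and to TFs (columns); the gene tree
#' is cut into \code{k} clusters. Rows and columns are pre-sorted
#' lexicographically so that merge ties break deterministically, making the
#' output invariant to the input order.
#'
#' @param m binary matrix from [buildTfMatrix] (>= 3 genes, >= 2 TFs).
#' @param k number of gene clusters to cut (default 2).
#' @return list with \code{gene_order} and \code{tf_order} (dendrogram leaf
#'   orders), \code{gene_clusters} (named integer cluster labels),
#'   \code{gene_hclust} and \code{tf_hclust}.
#' @export
twoWayCluster <- function(m, k = 2L) {
  if (nrow(m) < 3L || ncol(m) < 2L)
    stop("need at least 3 genes and 2 TFs")
  if (all(m == m[1L]))
    stop("no structure: matrix is constant")
  m <- m[order(rownames(m)), order(colnames(m)), drop = FALSE]
  hg <- stats::hclust(.pearson_dist(m), method = "average")
  ht <- stats::hclust(.pearson_dist(t(m)), method = "average")
  clusters <- stats::cutree(hg, k = k)
  list(gene_order = rownames(m)[hg$order],
       tf_order = colnames(m)[ht$order],
       gene_clusters = clusters,
       gene_hclust = hg,
       tf_hclust = ht)
}
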