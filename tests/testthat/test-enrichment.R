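# Hypergeometric ORA, bubble-term selection, TF matrix and clustering.

test_that("hypergeometric tail matches the closed form and enumeration", {
  uni <- letters[1:10]
  res <- ora(letters[1:5], list(s = letters[1:5]), uni)
  expect_equal(res$p_raw, 1 / choose(10, 5), tolerance = 1e-12)
  expect_equal(res$k, 5L)
  # exhaustive enumeration oracle on random small cases
  set.seed(61)
  for (i in 1:10) {
    N <- sample(5:12, 1)
    K <- sample(2:(N - 1), 1)
    n <- sample(2:(N - 1), 1)
    uni <- sprintf("u%02d", 1:N)
    memb <- uni[1:K]
    query <- sample(uni, n)
    k <- length(intersect(query, memb))
    if (k == 0) next
    res <- ora(query, list(s = memb), uni)
    expect_equal(res$p_raw, hyperTailOracle(k, K, N, n), tolerance = 1e-10)
  }
})

test_that("ORA drops empty overlaps and saturates at the universe", {
  uni <- sprintf("g%d", 1:20)
  coll <- list(hit = uni[1:5], miss = uni[11:15])
  res <- ora(uni[1:5], coll, uni)
  expect_identical(res$set_name, "hit")        # k = 0 sets are excluded
  resAll <- ora(uni, coll, uni)
  expect_true(all(resAll$p_raw == 1))
  expect_message(ora(c(uni[1:3], "outsider"), coll, uni), "outside")
  expect_error(ora("outsider", coll, uni), "empty query")
  # BH across tested sets, sorted by adjusted p
  set.seed(62)
  coll2 <- lapply(1:6, function(i) sample(uni, 8))
  names(coll2) <- paste0("s", 1:6)
  r2 <- ora(uni[1:6], coll2, uni)
  expect_equal(r2$p_adj, sort(bhOracle(r2$p_raw)), tolerance = 1e-12)
  expect_false(is.unsorted(r2$p_adj))
})

test_that("bubble-term selection applies the three published rules", {
  mk <- function(name, db, padj, genes, K = length(genes) + 2L) {
    data.frame(set_name = name, source_db = db, k = length(genes), K = K,
               n = 10L, N = 100L, p_raw = padj / 2, p_adj = padj,
               overlap_genes = I(list(genes)), stringsAsFactors = FALSE)
  }
  rows <- list(
    rbind(mk("termA", "GO", 0.01, c("g1", "g2", "g3")),
          mk("termB", "GO", 0.02, c("g4", "g5"), K = 4L)),
    rbind(mk("termA", "BioPlanet", 0.03, c("g1", "g2", "g3")),
          mk("termC", "BioPlanet", 0.005, c("g4", "g5"), K = 9L),
          mk("termD", "BioPlanet", 0.04, c("g7", "g8")))
  )
  out <- selectBubbleTerms(rows)
  # rule ii: duplicate name keeps the smaller adjusted p
  expect_equal(out$p_adj[out$set_name == "termA"], 0.01)
  expect_identical(out$source_db[out$set_name == "termA"], "GO")
  # rule iii: identical member sets collapse to the larger K (termC)
  expect_true("termC" %in% out$set_name)
  expect_false("termB" %in% out$set_name)
  # disjoint terms survive; output is a p_adj-sorted subset of the input
  expect_true("termD" %in% out$set_name)
  expect_false(is.unsorted(out$p_adj))
  # stability under input shuffling
  out2 <- selectBubbleTerms(rev(rows))
  expect_identical(out$set_name, out2$set_name)
  # explicit exclusion list
  out3 <- selectBubbleTerms(rows, exclude = "termD")
  expect_false("termD" %in% out3$set_name)
})

test_that("TF incidence matrix is built and filtered as specified", {
  edges <- data.frame(tf = c("tf1", "tf1", "tf2"),
                      target = c("g1", "g2", "g2"))
  m <- buildTfMatrix(c("g1", "g2", "g3"), edges)
  expect_identical(dimnames(m), list(c("g1", "g2"), c("tf1", "tf2")))
  expect_identical(as.vector(m), c(1L, 1L, 0L, 1L))   # g3 has no regulator
  # duplicate edges are idempotent
  m2 <- buildTfMatrix(c("g1", "g2", "g3"), rbind(edges, edges))
  expect_identical(m, m2)
  # expression filter drops a TF column entirely
  m3 <- suppressMessages(
    buildTfMatrix(c("g1", "g2"), edges, expressed_filter = "tf1"))
  expect_identical(colnames(m3), "tf1")
  expect_identical(attr(m3, "dropped_tfs"), character(0))
  expect_error(buildTfMatrix(c("g1", "g2"), edges,
                             expressed_filter = "tf9"), "no TF")
  expect_error(buildTfMatrix("g1", edges[0, ]), "empty")
})

test_that("two-way clustering recovers block structure deterministically", {
  blockA <- matrix(rep(c(1L, 1L, 0L, 0L), times = 4), 4, 4, byrow = TRUE)
  blockB <- matrix(rep(c(0L, 0L, 1L, 1L), times = 4), 4, 4, byrow = TRUE)
  m <- rbind(blockA, blockB)
  dimnames(m) <- list(sprintf("g%d", 1:8), sprintf("tf%d", 1:4))
  # a little asymmetry so rows within a block are not all identical
  m[1, 3] <- 1L; m[5, 1] <- 1L
  cl <- twoWayCluster(m, k = 2)
  lab <- cl$gene_clusters
  expect_equal(length(unique(lab[1:4])), 1L)
  expect_equal(length(unique(lab[5:8])), 1L)
  expect_false(lab[1] == lab[5])
  # permutation invariance up to label swap
  perm <- sample(nrow(m))
  cl2 <- twoWayCluster(m[perm, rev(seq_len(ncol(m)))], k = 2)
  expect_equal(ariOracle(lab[rownames(m)], cl2$gene_clusters[rownames(m)]),
               1)
  expect_identical(cl$gene_order, cl2$gene_order)
  # degenerate matrices
  expect_error(twoWayCluster(matrix(1L, 4, 3,
    dimnames = list(paste0("g", 1:4), paste0("t", 1:3)))), "no structure")
  mC <- m; mC[3, ] <- 1L   # constant row: Pearson undefined, max distance
  expect_message(twoWayCluster(mC, k = 2), "constant")
})

test_that("planted TF modules are recovered from synthetic data", {
  aris <- vapply(1:5, function(s) {
    b <- simulateDataset(smallConfig(s))
    perMut <- lapply(MUTANTS, function(m)
      standinTest(b$transcripts, b$design, m))
    common <- intersectDegs(
      lapply(perMut, function(d) applyThresholds(d)$pass_fc))$common
    expressed <- union(featureIds(b$proteins), featureIds(b$transcripts))
    mtx <- suppressMessages(buildTfMatrix(common, b$tfEdges, expressed))
    cl <- suppressMessages(twoWayCluster(mtx, k = 2))
    modGenes <- intersect(names(b$truth@geneModules), rownames(mtx))
    ariOracle(cl$gene_clusters[modGenes], b$truth@geneModules[modGenes])
  }, numeric(1))
  expect_gte(mean(aris), 0.9)
})
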