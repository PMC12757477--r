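# Protein-transcript matching and robust fold-change concordance.

test_that("feature matching is bookkept and ambiguity is fatal", {
  deps <- contrastDf(c("P1", "P2", "P3"), c(1, -2, 0.8),
                     c(0.001, 0.001, 0.001), c(0.01, 0.01, 0.01))
  degs <- contrastDf(c("G1", "G3"), c(1.1, 0), c(0.01, 0.9), c(0.05, 0.95))
  mapping <- data.frame(protein_id = c("P1", "P3"),
                        gene_id = c("G1", "G3"))
  pairs <- matchFeatures(deps, degs, mapping)
  expect_equal(nrow(pairs), 2L)
  expect_identical(attr(pairs, "n_unmapped"), 1L)     # P2
  expect_true(pairs$same_direction[pairs$protein_id == "P1"])
  # zero RNA fold change has no sign
  expect_false(pairs$same_direction[pairs$protein_id == "P3"])
  # protein mapped to a gene absent from the RNA table is counted
  mapping2 <- rbind(mapping, data.frame(protein_id = "P2", gene_id = "G9"))
  pairs2 <- matchFeatures(deps, degs, mapping2)
  expect_identical(attr(pairs2, "n_unmeasured"), 1L)
  # duplicate mapping rows name the offending protein
  bad <- rbind(mapping, data.frame(protein_id = "P1", gene_id = "G2"))
  expect_error(matchFeatures(deps, degs, bad), "P1")
  expect_error(matchFeatures(deps, degs, mapping[0, ]), "empty")
})

collinearPairs <- function(n, slope = 1, seed = 41) {
  set.seed(seed)
  x <- seq(-2, 2, length.out = n) + rnorm(n, 0, 1e-3)
  data.frame(protein_id = sprintf("P%02d", 1:n),
             gene_id = sprintf("G%02d", 1:n),
             log2fc_protein = x, log2fc_rna = slope * x,
             same_direction = TRUE, stringsAsFactors = FALSE)
}

test_that("collinear survivors give r = 1 and a gross outlier is removed", {
  pairs <- collinearPairs(20)
  clean <- removeOutliersAndCorrelate(pairs)
  expect_equal(clean$r, 1, tolerance = 1e-4)
  expect_equal(clean$n_removed, 0L)

  spiked <- pairs
  spiked[21, ] <- list("P99", "G99", 50 * max(pairs$log2fc_protein), 0.1,
                       TRUE)
  out <- removeOutliersAndCorrelate(spiked)
  # the spiked pair is the outlier, by our code and by brute-force median/MAD
  expect_true(out$pairs$is_outlier[out$pairs$protein_id == "P99"])
  expect_equal(out$n_removed, 1L)
  zOracle <- modZOracle(spiked$log2fc_protein)
  expect_identical(which(abs(zOracle) >= 3.5), 21L)
  expect_lt(abs(out$r - clean$r), 0.01)
})

test_that("contamination up to 10% barely moves the correlation", {
  pairs <- collinearPairs(30, seed = 42)
  r0 <- removeOutliersAndCorrelate(pairs)$r
  contaminated <- pairs
  for (k in 1:3)
    contaminated[30 + k, ] <- list(sprintf("PX%d", k), sprintf("GX%d", k),
                                   80 + 10 * k, -60 - 5 * k, FALSE)
  out <- removeOutliersAndCorrelate(contaminated)
  expect_equal(out$n_removed, 3L)
  expect_lt(abs(out$r - r0), 0.01)
})

test_that("outlier flagging is order-independent and idempotent", {
  pairs <- collinearPairs(25, seed = 43)
  pairs[26, ] <- list("PX", "GX", 90, -70, FALSE)
  out <- removeOutliersAndCorrelate(pairs)
  shuffled <- pairs[sample(nrow(pairs)), ]
  out2 <- removeOutliersAndCorrelate(shuffled)
  expect_setequal(out$pairs$protein_id[out$pairs$is_outlier],
                  out2$pairs$protein_id[out2$pairs$is_outlier])
  expect_equal(out$r, out2$r, tolerance = 1e-12)
  # a second pass over the survivors flags nothing new
  again <- removeOutliersAndCorrelate(
    out$pairs[!out$pairs$is_outlier,
              c("protein_id", "gene_id", "log2fc_protein", "log2fc_rna",
                "same_direction")])
  expect_equal(again$n_removed, 0L)
  expect_equal(again$r, out$r, tolerance = 1e-12)
})

test_that("r is invariant under positive affine transforms of either axis", {
  pairs <- collinearPairs(15, seed = 44)
  pairs$log2fc_rna <- pairs$log2fc_rna + rnorm(15, 0, 0.3)
  r0 <- removeOutliersAndCorrelate(pairs)$r
  scaled <- pairs
  scaled$log2fc_protein <- 3 * scaled$log2fc_protein + 5
  expect_equal(removeOutliersAndCorrelate(scaled)$r, r0, tolerance = 1e-12)
})

test_that("degenerate inputs are rejected", {
  pairs <- collinearPairs(3)
  expect_error(removeOutliersAndCorrelate(pairs), "at least 4")
})

test_that("fully concordant synthetic data yields high correlation", {
  rs <- vapply(1:3, function(s) {
    b <- simulateDataset(smallConfig(s, fracConcordant = 1))
    prot <- standinTest(b$proteins, b$design, MUTANTS)
    deps <- applyThresholds(prot)$pass_fc
    tran <- standinTest(b$transcripts, b$design, MUTANTS)
    pairs <- matchFeatures(prot[prot$feature_id %in% deps, ], tran,
                           b$mapping)
    removeOutliersAndCorrelate(pairs)$r
  }, numeric(1))
  expect_gte(min(rs), 0.9)
})
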