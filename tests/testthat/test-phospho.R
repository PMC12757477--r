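# ptmRS filter, protein-level normalization, modified Z-score and the two
# differential-phosphorylation strategies.

test_that("ptmRS filter is strictly greater-than", {
  rec <- data.frame(peptide_id = c("a", "b", "c"),
                    parent_protein_id = "P1", site_descriptor = "S1",
                    ptmrs_score = c(49, 50, 51))
  kept <- suppressMessages(filterPtmrs(rec))
  expect_identical(kept$peptide_id, "c")
  expect_identical(attr(kept, "n_removed"), 2L)
  expect_identical(nrow(filterPtmrs(rec[0, ])), 0L)
  rec$ptmrs_score <- 100
  expect_identical(filterPtmrs(rec)$peptide_id, rec$peptide_id)
})

test_that("protein-level normalization divides per sample and masks gaps", {
  pm <- matrix(c(10, 20, 7, 6, 8, 9), 3, 2,
               dimnames = list(c("pep1", "pep2", "pep3"), c("s1", "s2")))
  tm <- matrix(c(5, 4, 3, NA), 2, 2,
               dimnames = list(c("P1", "P2"), c("s1", "s2")))
  rec <- data.frame(peptide_id = c("pep1", "pep2", "pep3"),
                    parent_protein_id = c("P1", "P2", "P9"),
                    site_descriptor = "S1", ptmrs_score = 80)
  norm <- suppressMessages(normalizePhospho(
    tinyTable(pm, "phosphopeptide"), tinyTable(tm), rec))
  v <- abundances(norm)
  expect_equal(v["pep1", "s1"], 2)            # 10 / 5
  expect_equal(v["pep2", "s1"], 5)            # 20 / 4
  expect_true(is.na(v["pep2", "s2"]))         # parent missing in s2 only
  expect_false(is.na(v["pep1", "s2"]))
  expect_identical(attr(norm, "dropped"), "pep3")
  expect_identical(unname(parentProteins(norm)["pep1"]), "P1")
  # joint per-sample scaling of both tables cancels out
  pm2 <- pm; tm2 <- tm
  pm2[, "s1"] <- pm2[, "s1"] * 7
  tm2[, "s1"] <- tm2[, "s1"] * 7
  norm2 <- suppressMessages(normalizePhospho(
    tinyTable(pm2, "phosphopeptide"), tinyTable(tm2), rec))
  expect_equal(abundances(norm2), v)
})

test_that("modified Z-score matches hand computation and brute force", {
  z <- modifiedZscore(c(1, 2, 3, 4, 100))
  expect_equal(z[5], 65.4265, tolerance = 1e-6)
  expect_equal(modifiedZscore(c(5, 5, 5, 5)), rep(0, 4))
  # affine invariance
  set.seed(31)
  x <- rnorm(11)
  expect_equal(modifiedZscore(3 * x + 2), modifiedZscore(x),
               tolerance = 1e-12)
  expect_error(modifiedZscore(c(1, 2)), "at least 3")
  # brute-force sort-based oracle on short integer vectors (incl. MAD = 0)
  grid <- as.matrix(expand.grid(0:3, 0:3, 0:3, 0:3))
  for (i in seq_len(nrow(grid)))
    expect_equal(modifiedZscore(grid[i, ]), modZOracle(grid[i, ]),
                 tolerance = 1e-12)
})

test_that("strategy 1 computes the normalized difference as published", {
  set.seed(32)
  A <- rnorm(20); B <- 1.1 * A + rnorm(20, 0.8, 0.1)
  names(A) <- names(B) <- sprintf("p%02d", 1:20)
  res <- strategy1(A, B)
  # refitting the trend on (A, corrected B) gives intercept 0
  refit <- stats::lm(res$B ~ res$A)
  expect_lt(abs(coef(refit)[1]), 1e-9)
  # closed forms on a symmetric configuration whose OLS intercept is 0
  A0 <- c(a = 1, b = 2, c = -1, d = -2, e = 0.5, f = -0.5)
  B0 <- c(a = 3, b = 2, c = -3, d = -2, e = 0.5, f = -0.5)
  res0 <- strategy1(A0, B0)
  expect_lt(abs(attr(res0, "intercept")), 1e-9)
  expect_equal(res0$D[res0$peptide_id == "a"], 0.5)   # (3-1)/(1+3)
  expect_equal(res0$D[res0$peptide_id == "b"], 0)     # A = B, never outlier
  expect_false(res0$is_outlier[res0$peptide_id == "b"])
  expect_error(strategy1(A[1:2], B[1:2]), "at least 3")
  expect_error(strategy1(unname(A), unname(B)), "named")
})

test_that("strategy 1 excludes the undefined region near A + B = 0", {
  A <- c(p1 = 1, p2 = -1, p3 = 2, p4 = -2, p5 = 0.6, p6 = -0.6)
  B <- c(p1 = 1, p2 = -1, p3 = 2, p4 = -2, p5 = -0.6, p6 = 0.6)
  res <- suppressMessages(strategy1(A, B))   # p5, p6: A + B = 0 exactly
  expect_false(any(res$usable[res$peptide_id %in% c("p5", "p6")]))
  expect_true(all(is.na(res$D[res$peptide_id %in% c("p5", "p6")])))
  expect_true(all(res$usable[!res$peptide_id %in% c("p5", "p6")]))
  expect_message(strategy1(A, B), "excluded")
})

test_that("strategy 2 reproduces the closed-form worked example", {
  d <- tinyDesign(4, 3)
  pm <- matrix(c(rep(1, 4), rep(3, 3)), 1, 7,
               dimnames = list("pep1", sampleIds(d)))
  tm <- matrix(5, 1, 7, dimnames = list("P1", sampleIds(d)))
  rec <- data.frame(peptide_id = "pep1", parent_protein_id = "P1",
                    site_descriptor = "S1", ptmrs_score = 80)
  s2 <- dphosphoStrategy2(tinyTable(pm, "phosphopeptide"), tinyTable(tm),
                          rec, d, mutants = "T1")
  expect_equal(s2$n_ratios, 12L)                    # 3 x 4 pairs
  expect_equal(s2$log2fc_phospho, 2)                # log2(3 + 1)
  expect_equal(s2$log2fc_tot, 1)                    # log2(1 + 1)
  expect_equal(s2$effect, 1)
  expect_equal(s2$p_raw, 0)                         # zero variance, means differ
  # zero variance with equal means gives p = 1
  pm2 <- matrix(1, 1, 7, dimnames = list("pep1", sampleIds(d)))
  s2b <- dphosphoStrategy2(tinyTable(pm2, "phosphopeptide"), tinyTable(tm),
                           rec, d, mutants = "T1")
  expect_equal(s2b$p_raw, 1)
  expect_equal(s2b$effect, 0)
})

test_that("strategy 2 p-values match an independent t-test construction", {
  set.seed(33)
  d <- tinyDesign(4, 3)
  pm <- matrix(2^rnorm(7, 12, 0.4), 1, 7,
               dimnames = list("pep1", sampleIds(d)))
  tm <- matrix(2^rnorm(7, 20, 0.4), 1, 7,
               dimnames = list("P1", sampleIds(d)))
  rec <- data.frame(peptide_id = "pep1", parent_protein_id = "P1",
                    site_descriptor = "S1", ptmrs_score = 80)
  s2 <- dphosphoStrategy2(tinyTable(pm, "phosphopeptide"), tinyTable(tm),
                          rec, d, mutants = "T1")
  wt <- sampleIds(d)[1:4]; mut <- sampleIds(d)[5:7]
  rp <- log2(as.vector(outer(pm[1, mut], pm[1, wt], "/")) + 1)
  rt <- log2(as.vector(outer(tm[1, mut], tm[1, wt], "/")) + 1)
  ref <- stats::t.test(rp, rt, var.equal = TRUE)
  expect_equal(s2$p_raw, ref$p.value, tolerance = 1e-10)
  expect_equal(s2$effect, mean(rp) - mean(rt), tolerance = 1e-12)
  # Bonferroni: adjusted p = raw p times the family size, capped at 1
  expect_equal(s2$p_adj, min(1, s2$p_raw * nrow(s2)))
})

test_that("proportional peptide has vanishing effect; label swap flips sign", {
  set.seed(34)
  d <- tinyDesign(4, 3)
  prot <- 2^(20 + matrix(rnorm(7, 0, 0.3), 1) +
             c(rep(0, 4), rep(2, 3)))   # protein itself is DE
  dimnames(prot) <- list("P1", sampleIds(d))
  pep <- prot * 0.3                      # perfectly proportional peptide
  rownames(pep) <- "pep1"
  rec <- data.frame(peptide_id = "pep1", parent_protein_id = "P1",
                    site_descriptor = "S1", ptmrs_score = 80)
  s2 <- dphosphoStrategy2(tinyTable(pep, "phosphopeptide"), tinyTable(prot),
                          rec, d, mutants = "T1")
  expect_lt(abs(s2$effect), 0.05)
  # swapping the roles of mutant and reference flips the effect sign; with a
  # vanishing ratio pseudocount the antisymmetry is exact
  dSwap <- sampleDesign(sampleIds(d),
                        c(rep("MUT", 4), rep("REF", 3)),
                        c(1:4, 1:3), reference = "REF")
  pepB <- pep; pepB[1, ] <- pep[1, ] * 2^c(rep(0, 4), rep(1.5, 3))
  thTiny <- thresholds(pseudocountRatio = 1e-9)
  s2f <- dphosphoStrategy2(tinyTable(pepB, "phosphopeptide"),
                           tinyTable(prot), rec, d, mutants = "T1",
                           th = thTiny)
  s2r <- dphosphoStrategy2(tinyTable(pepB, "phosphopeptide"),
                           tinyTable(prot), rec, dSwap, mutants = "MUT",
                           th = thTiny)
  expect_equal(s2f$effect, -s2r$effect, tolerance = 1e-6)
  # with the default pseudocount of 1 the flip still holds in sign
  s2f1 <- dphosphoStrategy2(tinyTable(pepB, "phosphopeptide"),
                            tinyTable(prot), rec, d, mutants = "T1")
  s2r1 <- dphosphoStrategy2(tinyTable(pepB, "phosphopeptide"),
                            tinyTable(prot), rec, dSwap, mutants = "MUT")
  expect_true(sign(s2f1$effect) == -sign(s2r1$effect))
})

test_that("consensus tiers follow the two-strategy, two-condition rule", {
  mk1 <- function(cond, flagged) {
    data.frame(peptide_id = c("p1", "p2", "p3"), condition = cond,
               is_outlier = c("p1", "p2", "p3") %in% flagged,
               stringsAsFactors = FALSE)
  }
  calls1 <- list(T1 = mk1("T1", "p1"), T5 = mk1("T5", c("p1", "p2")))
  calls2 <- data.frame(peptide_id = rep(c("p1", "p2", "p3"), 2),
                       condition = rep(c("T1", "T5"), each = 3),
                       is_significant = c(TRUE, FALSE, FALSE,
                                          TRUE, FALSE, FALSE),
                       stringsAsFactors = FALSE)
  cons <- dphosphoConsensus(calls1, calls2)
  expect_identical(cons$confidence[cons$peptide_id == "p1"], "high")
  expect_identical(cons$conditions_detected[cons$peptide_id == "p1"],
                   "T1,T5")
  expect_identical(cons$confidence[cons$peptide_id == "p2"], "candidate")
  expect_false("p3" %in% cons$peptide_id)
  # no flags anywhere: empty call table
  none2 <- calls2; none2$is_significant <- FALSE
  none1 <- lapply(calls1, function(d) { d$is_outlier <- FALSE; d })
  expect_identical(nrow(dphosphoConsensus(none1, none2)), 0L)
  # disjoint peptide universes indicate an upstream misjoin
  other <- calls2; other$peptide_id <- paste0("q", 1:6)
  expect_error(dphosphoConsensus(calls1, other), "disjoint")
})

test_that("planted peptides are recovered on the synthetic benchmark", {
  sens1 <- c(); sensU <- c(); fdrBoth <- c()
  for (s in 1:5) {
    b <- simulateDataset(smallConfig(s))
    rec <- suppressMessages(filterPtmrs(b$phosphoRecords))
    s1 <- suppressMessages(dphosphoStrategy1(
      b$phospho, b$proteins, rec, b$design, MUTANTS))
    s2 <- suppressMessages(dphosphoStrategy2(
      b$phospho, b$proteins, rec, b$design, MUTANTS))
    h1 <- unique(unlist(lapply(s1, function(d) d$peptide_id[d$is_outlier])))
    h2 <- unique(s2$peptide_id[s2$is_significant])
    cons <- dphosphoConsensus(s1, s2)
    both <- cons$peptide_id[cons$by_strategy1 & cons$by_strategy2]
    tr <- b$truth@dphosphoIds
    sens1 <- c(sens1, mean(tr %in% h1))
    sensU <- c(sensU, mean(tr %in% union(h1, h2)))
    fdrBoth <- c(fdrBoth, if (length(both)) mean(!(both %in% tr)) else 0)
  }
  expect_gte(mean(sens1), 0.8)
  expect_gte(mean(sensU), 0.8)
  expect_lte(mean(fdrBoth), 0.25)
})
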