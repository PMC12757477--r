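# Shared fixtures and independent oracles for the test suite.

MUTANTS <- c("T1", "T5", "T12", "T15", "Q79KW80R")

# small but fully structured simulation for fast recovery checks
smallConfig <- function(seed, ...) {
  simulationConfig(seed = seed, nProteins = 300L, nTranscripts = 800L,
                   nPhospho = 40L, nGof = 20L, nLof = 20L, nTfs = 15L, ...)
}

nullConfig <- function(seed, ...) {
  simulationConfig(seed = seed, fracDep = 0, fracDeg = 0, fracDphospho = 0,
                   fracConcordant = 0, nGof = 0L, nLof = 0L, ...)
}

# two-condition design: nA reference-condition samples, nB test samples
tinyDesign <- function(nA = 4L, nB = 3L, ref = "WT", test = "T1") {
  sampleDesign(c(sprintf("%s_r%d", ref, seq_len(nA)),
                 sprintf("%s_r%d", test, seq_len(nB))),
               c(rep(ref, nA), rep(test, nB)),
               c(seq_len(nA), seq_len(nB)), reference = ref)
}

tinyTable <- function(values, kind = "protein") abundanceTable(values, kind)

# independent BH oracle: sorted p * m / rank with cumulative minimum
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- rev(cummin(rev(p[o] * m / seq_len(m))))
  pmin(1, adj)[order(o)]
}

# brute-force modified Z: explicit sort-based medians, no shared code path
modZOracle <- function(x) {
  med_sort <- function(v) {
    v <- sort(v)
    n <- length(v)
    if (n %% 2L == 1L) v[(n + 1L) / 2L] else (v[n / 2L] + v[n / 2L + 1L]) / 2
  }
  med <- med_sort(x)
  mad0 <- med_sort(abs(x - med))
  if (mad0 > 0) return(0.6745 * (x - med) / mad0)
  meanAD <- sum(abs(x - sum(x) / length(x))) / length(x)
  if (meanAD == 0) return(rep(0, length(x)))
  (x - med) / (1.253314 * meanAD)
}

# exhaustive hypergeometric upper tail: enumerate all C(N, n) draws
hyperTailOracle <- function(k, K, N, n) {
  draws <- utils::combn(N, n)
  members <- seq_len(K)   # WLOG the first K universe elements are the set
  hits <- apply(draws, 2L, function(d) sum(d %in% members))
  mean(hits >= k)
}

# adjusted Rand index from the pair-counting contingency formula
ariOracle <- function(a, b) {
  tab <- table(a, b)
  sumij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  npairs <- choose(sum(tab), 2)
  expected <- ai * bj / npairs
  (sumij - expected) / ((ai + bj) / 2 - expected)
}

# contrast-result data.frame builder
contrastDf <- function(ids, fc, p, padj = p, th = thresholds()) {
  data.frame(feature_id = ids, log2fc = fc, p_raw = p, p_adj = padj,
             direction = ifelse(padj < th@alphaAdj &
                                abs(fc) >= th@log2fcMin,
                                ifelse(fc > 0, "up", "down"), "unchanged"),
             stringsAsFactors = FALSE)
}
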