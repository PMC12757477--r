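# Differential-expression stand-in test, threshold filtering and DEG-set
# intersection.

.auto_eps <- function(m, th) {
  eps <- th@pseudocountAbund
  if (is.na(eps)) {
    pos <- m[!is.na(m) & m > 0]
    eps <- if (length(pos)) min(pos) / 2 else .Machine$double.eps
  }
  eps
}

.direction_call <- function(log2fc, p_adj, th) {
  ifelse(!is.na(p_adj) & p_adj < th@alphaAdj & abs(log2fc) >= th@log2fcMin,
         ifelse(log2fc > 0, "up", "down"), "unchanged")
}

#' Per-feature two-group differential test on log2 abundances
#'
#' A stand-in for the study's external DE tools so that synthetic end-to-end
#' runs need no downloads: per feature, the log2 fold change is
#' \code{log2((mean_test + eps) / (mean_ref + eps))} on the raw scale, and a
#' p-value is computed on log2-transformed abundances. Real DE result tables
#' are accepted directly by the downstream stages via [readContrastResult].
#'
#' Two tests are available. \code{"moderated"} (default) is limma's
#' empirical-Bayes moderated t on the log2 values, which shares variance
#' information across features the way dedicated DE tools do and is the
#' sensible choice at 3-4 replicates. \code{"welch"} is a per-feature
#' unequal-variance t-test. P-values are BH-adjusted across features.
#'
#' Features with any missing value in either group are dropped (count
#' reported in the \code{"n_dropped"} attribute). For the Welch test,
#' zero variance on both sides gives p = 1 when the means are equal and
#' p = 0 otherwise.
#'
#' @param table an [AbundanceTable-class].
#' @param design a [SampleDesign-class] covering the table's samples.
#' @param test condition label(s) of the test group (several labels pool
#'   their samples, e.g. all mutants).
#' @param reference condition label(s) of the reference group; defaults to
#'   the design's reference condition.
#' @param th a [Thresholds-class] (used for the pseudocount and the
#'   direction call).
#' @param method \code{"moderated"} or \code{"welch"}.
#' @return contrast-result data.frame (feature_id, log2fc, p_raw, p_adj,
#'   direction) with attribute \code{n_dropped}.
#' @examples
#' b <- simulateDataset(simulationConfig(seed = 1, nProteins = 50,
#'   nTranscripts = 150, nPhospho = 10, nGof = 5, nLof = 5, nTfs = 6))
#' res <- standinTest(b$proteins, b$design,
#'                    test = c("T1", "T5", "T12", "T15", "Q79KW80R"))
#' head(res)
#' @export
standinTest <- function(table, design, test,
                        reference = referenceCondition(design),
                        th = thresholds(),
                        method = c("moderated", "welch")) {
  method <- match.arg(method)
  m <- abundances(table)
  testS <- intersect(samplesFor(design, test), colnames(m))
  refS <- intersect(samplesFor(design, reference), colnames(m))
  if (length(testS) < 2L || length(refS) < 2L)
    stop("need at least 2 replicates on each side of the contrast")
  x <- m[, testS, drop = FALSE]
  y <- m[, refS, drop = FALSE]
  keep <- stats::complete.cases(x) & stats::complete.cases(y)
  nDropped <- sum(!keep)
  if (nDropped)
    message(nDropped, " feature(s) dropped for missing values")
  if (!any(keep)) stop("no feature is complete on both sides")
  x <- x[keep, , drop = FALSE]
  y <- y[keep, , drop = FALSE]

  eps <- .auto_eps(m, th)
  log2fc <- log2((rowMeans(x) + eps) / (rowMeans(y) + eps))
  lx <- log2(x + eps)   # eps guards exact zeros; negligible elsewhere
  ly <- log2(y + eps)

  if (method == "welch") {
    n1 <- ncol(lx); n2 <- ncol(ly)
    m1 <- rowMeans(lx); m2 <- rowMeans(ly)
    v1 <- apply(lx, 1L, stats::var); v2 <- apply(ly, 1L, stats::var)
    se2 <- v1 / n1 + v2 / n2
    tt <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- 2 * stats::pt(-abs(tt), df)
    degen <- se2 == 0
    p[degen] <- ifelse(m1[degen] == m2[degen], 1, 0)
  } else {
    groups <- factor(c(rep("test", ncol(lx)), rep("ref", ncol(ly))),
                     levels = c("ref", "test"))
    dm <- stats::model.matrix(~groups)
    fit <- limma::eBayes(limma::lmFit(cbind(lx, ly), dm))
    p <- fit$p.value[, 2L]
    # all-equal features have no information; don't let them drive the prior
    flat <- apply(cbind(lx, ly), 1L, function(r) all(r == r[1L]))
    p[flat] <- 1
  }
  p_adj <- stats::p.adjust(p, method = "BH")
  res <- data.frame(feature_id = rownames(x),
                    log2fc = as.numeric(log2fc),
                    p_raw = as.numeric(p),
                    p_adj = as.numeric(p_adj),
                    direction = .direction_call(log2fc, p_adj, th),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "n_dropped") <- nDropped
  res
}

#' Filter a contrast result into DE categories
#'
#' Applies the two published filters in sequence: significance (BH-adjusted
#' p below \code{alphaAdj}) and effect size (|log2FC| at or above
#' \code{log2fcMin}, i.e. fold change 1.5 at the default 0.585). Features
#' significant by p but failing the fold-change filter are kept in the
#' report, since both counts are meaningful.
#'
#' @param results contrast-result data.frame.
#' @param th a [Thresholds-class].
#' @return a \code{DEFilterReport} list: counts (\code{n_significant},
#'   \code{n_pass_fc}, \code{n_up}, \code{n_down}) and id vectors
#'   (\code{significant}, \code{pass_fc}, \code{up}, \code{down}).
#' @examples
#' res <- data.frame(feature_id = c("a", "b"), log2fc = c(0.6, 0.5),
#'                   p_raw = c(0.001, 0.001), p_adj = c(0.04, 0.04),
#'                   direction = c("up", "unchanged"))
#' applyThresholds(res)   # b is significant but fails the FC filter
#' @export
applyThresholds <- function(results, th = thresholds()) {
  validateContrastResult(results)
  sig <- !is.na(results$p_adj) & results$p_adj < th@alphaAdj
  fc <- sig & abs(results$log2fc) >= th@log2fcMin
  up <- fc & results$log2fc > 0
  down <- fc & results$log2fc < 0
  report <- list(
    n_significant = sum(sig),
    n_pass_fc = sum(fc),
    n_up = sum(up),
    n_down = sum(down),
    significant = results$feature_id[sig],
    pass_fc = results$feature_id[fc],
    up = results$feature_id[up],
    down = results$feature_id[down],
    thresholds = c(alpha_adj = th@alphaAdj, log2fc_min = th@log2fcMin)
  )
  class(report) <- "DEFilterReport"
  report
}

#' @export
print.DEFilterReport <- function(x, ...) {
  cat(sprintf(
    "DEFilterReport: %d significant (adj p < %g); %d pass |log2FC| >= %g (%d up, %d down)\n",
    x$n_significant, x$thresholds["alpha_adj"], x$n_pass_fc,
    x$thresholds["log2fc_min"], x$n_up, x$n_down))
  invisible(x)
}

#' Intersect per-mutant DEG sets
#'
#' The genes differentially expressed in every mutant-versus-reference
#' comparison, plus the pairwise overlap matrix.
#'
#' @param per_mutant named list of character vectors (one DEG id set per
#'   mutant condition).
#' @return list with \code{common} (the intersection, sorted) and
#'   \code{overlap} (symmetric matrix of pairwise intersection sizes; the
#'   diagonal holds set sizes).
#' @examples
#' intersectDegs(list(T1 = c("a", "b", "c"), T5 = c("b", "c"),
#'                    T12 = c("c", "b", "d")))$common
#' @export
intersectDegs <- function(per_mutant) {
  if (!is.list(per_mutant) || length(per_mutant) < 2L)
    stop("need DEG sets for at least 2 mutants")
  sets <- lapply(per_mutant, function(s) unique(as.character(s)))
  common <- sort(Reduce(intersect, sets))
  k <- length(sets)
  overlap <- matrix(0L, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k)) for (j in seq_len(k))
    overlap[i, j] <- length(intersect(sets[[i]], sets[[j]]))
  list(common = common, overlap = overlap)
}
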