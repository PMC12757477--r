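# Differential-phosphorylation core: ptmRS filtering, protein-level
# normalization, the Iglewicz-Hoaglin modified Z-score, and the two calling
# strategies with consensus tiers.

#' Filter phosphopeptide records on ptmRS localization score
#'
#' Strictly-greater-than filter: a record is kept only if
#' \code{ptmrs_score > ptmrsMin} (score exactly at the cutoff is excluded).
#'
#' @param records phosphopeptide record data.frame (see
#'   [readPhosphoRecords]).
#' @param th a [Thresholds-class]; default cutoff 50.
#' @return the retained records, with attribute \code{n_removed}.
#' @examples
#' rec <- data.frame(peptide_id = c("a", "b", "c"),
#'                   parent_protein_id = "P1", site_descriptor = "S1",
#'                   ptmrs_score = c(49, 50, 51))
#' filterPtmrs(rec)$peptide_id   # only "c": the filter is strict
#' @export
filterPtmrs <- function(records, th = thresholds()) {
  if (any(is.na(records$ptmrs_score)))
    stop("ptmrs_score must be present for every record")
  keep <- records$ptmrs_score > th@ptmrsMin
  if (any(!keep))
    message(sum(!keep), " phosphopeptide(s) removed by ptmRS filter (> ",
            th@ptmrsMin, "): ",
            paste(records$peptide_id[!keep], collapse = ", "))
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Normalize phosphopeptide abundances to parent-protein level
#'
#' Per sample, the normalized value is phosphopeptide abundance divided by
#' the abundance of the parent protein in the same sample. A value is
#' present only where both measurements are; samples where the parent
#' protein is missing are masked as missing. Peptides whose parent protein
#' is absent from the protein table altogether are dropped (ids reported in
#' the \code{"dropped"} attribute). Because both tables are divided
#' sample-by-sample, the result is invariant to any per-sample global
#' scaling applied jointly to both tables.
#'
#' @param phospho phosphopeptide [AbundanceTable-class].
#' @param protein total-protein [AbundanceTable-class].
#' @param records phosphopeptide records mapping peptides to parents.
#' @return a [NormalizedPhosphoTable-class].
#' @export
normalizePhospho <- function(phospho, protein, records) {
  pm <- abundances(phospho)
  tm <- abundances(protein)
  records <- records[records$peptide_id %in% rownames(pm), , drop = FALSE]
  resolvable <- records$parent_protein_id %in% rownames(tm)
  dropped <- records$peptide_id[!resolvable]
  if (length(dropped))
    message(length(dropped),
            " peptide(s) dropped: parent protein not quantified: ",
            paste(dropped, collapse = ", "))
  records <- records[resolvable, , drop = FALSE]
  if (!nrow(records)) stop("no peptide has a quantified parent protein")
  shared <- intersect(colnames(pm), colnames(tm))
  parentOf <- stats::setNames(records$parent_protein_id, records$peptide_id)
  num <- pm[records$peptide_id, shared, drop = FALSE]
  den <- tm[records$parent_protein_id, shared, drop = FALSE]
  bad <- !is.na(den) & den <= 0
  den[bad] <- NA   # zero protein abundance cannot support a ratio
  out <- new("NormalizedPhosphoTable",
             values = num / den, kind = "phosphopeptide",
             parent = parentOf)
  attr(out, "dropped") <- dropped
  out
}

#' Iglewicz-Hoaglin modified Z-score
#'
#' \eqn{z_i = 0.6745 (x_i - \tilde{x}) / \mathrm{MAD}} with
#' \eqn{\mathrm{MAD} = \mathrm{median}(|x - \tilde{x}|)} (unscaled). When the
#' MAD is zero the recommended fallback is used:
#' \eqn{z_i = (x_i - \tilde{x}) / (1.253314 \cdot \mathrm{meanAD})} with
#' meanAD the mean absolute deviation about the mean. An all-equal vector
#' yields all zeros. The statistic is invariant under affine maps of x.
#'
#' @param x numeric vector, length at least 3, no missing values.
#' @return numeric vector of modified Z-scores.
#' @examples
#' modifiedZscore(c(1, 2, 3, 4, 100))[5]   # 0.6745 * 97 / 1 = 65.4265
#' @export
modifiedZscore <- function(x) {
  if (length(x) < 3L)
    stop("modified Z-score needs at least 3 values")
  if (any(is.na(x))) stop("x must not contain missing values")
  med <- stats::median(x)
  mad0 <- stats::median(abs(x - med))
  if (mad0 > 0)
    return(0.6745 * (x - med) / mad0)
  meanAD <- mean(abs(x - mean(x)))
  if (meanAD == 0)
    return(rep(0, length(x)))
  (x - med) / (1.253314 * meanAD)
}

#' Per-feature log2 fold change of condition means
#'
#' \code{log2((mean_test + eps) / (mean_ref + eps))} with means taken over
#' the present (non-missing) replicate values of each feature.
#'
#' @param table an [AbundanceTable-class] (or normalized phospho table).
#' @param design a [SampleDesign-class].
#' @param test,reference condition labels.
#' @param th a [Thresholds-class] (supplies the pseudocount rule).
#' @param stat \code{"mean"} (default) or \code{"median"} replicate summary.
#' @return named numeric vector of log2 fold changes.
#' @export
contrastLog2fc <- function(table, design, test,
                           reference = referenceCondition(design),
                           th = thresholds(), stat = c("mean", "median")) {
  stat <- match.arg(stat)
  m <- abundances(table)
  testS <- intersect(samplesFor(design, test), colnames(m))
  refS <- intersect(samplesFor(design, reference), colnames(m))
  if (!length(testS) || !length(refS))
    stop("contrast has no samples in the table")
  eps <- .auto_eps(m, th)
  f <- if (stat == "mean") rowMeans else
    function(mm, na.rm) apply(mm, 1L, stats::median, na.rm = na.rm)
  log2((f(m[, testS, drop = FALSE], na.rm = TRUE) + eps) /
       (f(m[, refS, drop = FALSE], na.rm = TRUE) + eps))
}

#' Strategy 1: normalized-difference outliers on the expression/phosphorylation scatter
#'
#' Given, per peptide, the parent protein's expression log2FC (A) and the
#' phosphorylation log2FC (B), an ordinary least-squares trend line of B on
#' A is fitted and its intercept subtracted from B, so the refitted trend
#' passes through the origin. The normalized difference
#' \eqn{D = (\max(A,B) - \min(A,B)) / (A + B)} is then computed per peptide,
#' and peptides whose modified Z-score of D reaches \code{zDphospho} in
#' magnitude are flagged as differentially phosphorylated. Peptides with
#' \eqn{|A + B| < \delta} are excluded from D (the statistic is undefined
#' there), not clamped.
#'
#' @param A named numeric: per-peptide log2FC of parent-protein expression
#'   (mutant versus reference).
#' @param B_raw named numeric on the same peptides: per-peptide log2FC of
#'   phosphorylation.
#' @param th a [Thresholds-class].
#' @param delta exclusion half-width around A + B = 0 (default 1e-6).
#' @param robust_fit use a Theil-Sen line instead of OLS for the intercept
#'   correction.
#' @return data.frame (peptide_id, A, B_raw, B, D, z, is_outlier, usable)
#'   with attributes \code{intercept} and \code{slope}. Excluded peptides
#'   have \code{usable = FALSE} and NA statistics.
#' @examples
#' A <- c(p1 = 1, p2 = 2, p3 = 0.5, p4 = 1)
#' B <- c(p1 = 3, p2 = 2, p3 = 0.5, p4 = 1)
#' strategy1(A, B)$D[1]   # (3 - 1) / (1 + 3) = 0.5
#' @export
strategy1 <- function(A, B_raw, th = thresholds(), delta = 1e-6,
                      robust_fit = FALSE) {
  if (is.null(names(A)) || !identical(names(A), names(B_raw)))
    stop("A and B_raw must be named and aligned on the same peptides")
  ok <- !is.na(A) & !is.na(B_raw)
  if (sum(ok) < 3L)
    stop("strategy 1 needs at least 3 peptides with both log2FCs")
  a <- A[ok]; b <- B_raw[ok]
  if (robust_fit) {
    slopes <- outer(b, b, "-") / outer(a, a, "-")
    slope <- stats::median(slopes[upper.tri(slopes) & is.finite(slopes)])
    intercept <- stats::median(b - slope * a)
  } else {
    fit <- stats::lm.fit(cbind(1, a), b)
    intercept <- fit$coefficients[1L]
    slope <- fit$coefficients[2L]
  }
  B <- B_raw - intercept
  s <- A + B
  usable <- ok & abs(s) >= delta
  if (any(ok & !usable))
    message(sum(ok & !usable), " peptide(s) excluded from D: |A + B| < ",
            delta)
  if (sum(usable) < 3L)
    stop("fewer than 3 peptides usable for the normalized difference")
  D <- rep(NA_real_, length(A))
  D[usable] <- (pmax(A, B)[usable] - pmin(A, B)[usable]) / s[usable]
  z <- rep(NA_real_, length(A))
  z[usable] <- modifiedZscore(D[usable])
  out <- data.frame(peptide_id = names(A), A = as.numeric(A),
                    B_raw = as.numeric(B_raw), B = as.numeric(B),
                    D = D, z = z,
                    is_outlier = !is.na(z) & abs(z) >= th@zDphospho,
                    usable = usable,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "intercept") <- unname(intercept)
  attr(out, "slope") <- unname(slope)
  out
}

#' Strategy 1 across mutant conditions
#'
#' For each mutant condition, computes A as the parent protein's log2FC
#' (mutant versus reference, on the total-protein table) and B as the
#' peptide's phosphorylation log2FC on the phosphopeptide abundances, then
#' runs [strategy1].
#'
#' @param phospho phosphopeptide [AbundanceTable-class] (raw abundances;
#'   the trend-line correction handles the peptide/protein offset).
#' @param protein total-protein [AbundanceTable-class].
#' @param records phosphopeptide records (peptide to parent protein).
#' @param design a [SampleDesign-class].
#' @param mutants mutant condition labels; default: every condition except
#'   the design reference and the first condition (the no-transgene control).
#' @param th a [Thresholds-class].
#' @param ... passed to [strategy1].
#' @return named list of per-condition [strategy1] data.frames.
#' @export
dphosphoStrategy1 <- function(phospho, protein, records, design,
                              mutants = NULL, th = thresholds(), ...) {
  if (is.null(mutants))
    mutants <- setdiff(conditions(design),
                       c(conditions(design)[1L], referenceCondition(design)))
  records <- records[records$peptide_id %in% featureIds(phospho) &
                     records$parent_protein_id %in% featureIds(protein), ,
                     drop = FALSE]
  out <- lapply(mutants, function(cond) {
    aProt <- contrastLog2fc(protein, design, cond, th = th)
    bPep <- contrastLog2fc(phospho, design, cond, th = th)
    A <- stats::setNames(aProt[records$parent_protein_id],
                         records$peptide_id)
    B <- stats::setNames(bPep[records$peptide_id], records$peptide_id)
    res <- strategy1(A, B, th = th, ...)
    res$condition <- cond
    res
  })
  stats::setNames(out, mutants)
}

# all-pairs ratio statistics for one peptide/feature in one condition
.allpairs_log2 <- function(mutVals, refVals, pseudo) {
  mutVals <- mutVals[!is.na(mutVals)]
  refVals <- refVals[!is.na(refVals)]
  if (length(mutVals) < 2L || length(refVals) < 2L) return(NULL)
  log2(as.vector(outer(mutVals, refVals, "/")) + pseudo)
}

# classical equal-variance two-sample t with the degenerate-variance rule
.student_t <- function(x, y, var_equal = TRUE) {
  n1 <- length(x); n2 <- length(y)
  m1 <- mean(x); m2 <- mean(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (v1 == 0 && v2 == 0)
    return(if (m1 == m2) 1 else 0)
  if (var_equal) {
    sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    tt <- (m1 - m2) / sqrt(sp * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se2 <- v1 / n1 + v2 / n2
    tt <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  2 * stats::pt(-abs(tt), df)
}

#' Strategy 2: all-pairs ratio test per peptide and condition
#'
#' For each peptide, every ratio of its abundance in a mutant replicate over
#' its abundance in a reference replicate is formed (n_mut x n_ref ratios);
#' the same is done for the parent protein's total abundance. A pseudocount
#' (default 1) is added to each ratio before log2. The peptide's
#' phosphorylation log2FC and total-protein log2FC are the means of the two
#' transformed sets; the reported effect is their difference — this
#' subtraction is the protein-level normalization at the fold-change scale,
#' so a peptide that merely follows its parent protein's expression change
#' has effect near 0. A classical Student's t-test between the two ratio
#' sets gives the raw p-value; Bonferroni correction is applied across all
#' peptide-by-condition tests of the run (the widest family).
#'
#' Note the ratio sets are built from n_mut + n_ref measurements, so their
#' elements are not independent; the nominal p-values of this published
#' procedure are anticonservative (see the package vignette).
#'
#' @param phospho phosphopeptide [AbundanceTable-class] (run-normalized
#'   abundances as exported by label-free quantification tools).
#' @param protein total-protein [AbundanceTable-class].
#' @param records phosphopeptide records mapping peptides to parent
#'   proteins; may be omitted when \code{phospho} is a
#'   [NormalizedPhosphoTable-class] carrying its own parent map.
#' @param design a [SampleDesign-class].
#' @param mutants mutant condition labels (default as in
#'   [dphosphoStrategy1]).
#' @param th a [Thresholds-class].
#' @param var_equal classical equal-variance Student t (default, as
#'   published); \code{FALSE} for Welch.
#' @return data.frame with one row per peptide x condition: peptide_id,
#'   condition, n_ratios, log2fc_phospho, log2fc_tot, effect, p_raw, p_adj
#'   (Bonferroni, family = all rows), is_significant.
#' @export
dphosphoStrategy2 <- function(phospho, protein, records = NULL, design,
                              mutants = NULL, th = thresholds(),
                              var_equal = TRUE) {
  if (is.null(mutants))
    mutants <- setdiff(conditions(design),
                       c(conditions(design)[1L], referenceCondition(design)))
  ref <- referenceCondition(design)
  nm <- abundances(phospho)
  tm <- abundances(protein)
  parents <- if (!is.null(records))
    stats::setNames(records$parent_protein_id,
                    records$peptide_id)[rownames(nm)]
  else if (is(phospho, "NormalizedPhosphoTable")) parentProteins(phospho)
  else stop("records are required to resolve parent proteins")
  keep <- !is.na(parents) & parents %in% rownames(tm)
  nm <- nm[rownames(nm)[keep], , drop = FALSE]
  parents <- parents[keep]
  pseudo <- th@pseudocountRatio
  refS <- intersect(samplesFor(design, ref), colnames(nm))
  refST <- intersect(samplesFor(design, ref), colnames(tm))
  rows <- list()
  skipped <- 0L
  for (cond in mutants) {
    mutS <- intersect(samplesFor(design, cond), colnames(nm))
    mutST <- intersect(samplesFor(design, cond), colnames(tm))
    for (pep in rownames(nm)) {
      rp <- .allpairs_log2(nm[pep, mutS], nm[pep, refS], pseudo)
      rt <- .allpairs_log2(tm[parents[pep], mutST],
                           tm[parents[pep], refST], pseudo)
      if (is.null(rp) || is.null(rt)) {
        skipped <- skipped + 1L
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        peptide_id = pep, condition = cond,
        n_ratios = length(rp),
        log2fc_phospho = mean(rp), log2fc_tot = mean(rt),
        effect = mean(rp) - mean(rt),
        p_raw = .student_t(rp, rt, var_equal),
        stringsAsFactors = FALSE)
    }
  }
  if (skipped)
    message(skipped, " peptide x condition test(s) skipped: fewer than 2 ",
            "usable replicates on a side")
  if (!length(rows)) stop("no peptide x condition test could be computed")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  m <- nrow(out)
  out$p_adj <- pmin(1, out$p_raw * m)
  out$is_significant <- out$p_adj < th@alphaAdj
  attr(out, "bonferroni_family") <- m
  out
}

#' Consensus differential-phosphorylation calls
#'
#' Combines the per-condition calls of the two strategies. A peptide's
#' detected conditions are those where either strategy flagged it; the
#' confidence tier is \code{"high"} when the peptide was flagged by both
#' strategies and detected in at least two mutant conditions, otherwise
#' \code{"candidate"}. Peptides flagged by neither strategy are omitted.
#'
#' @param calls1 list of per-condition [strategy1] data.frames (from
#'   [dphosphoStrategy1]).
#' @param calls2 [dphosphoStrategy2] data.frame.
#' @return data.frame (peptide_id, conditions_detected, n_conditions,
#'   by_strategy1, by_strategy2, confidence), sorted by confidence then
#'   peptide id.
#' @export
dphosphoConsensus <- function(calls1, calls2) {
  s1 <- do.call(rbind, lapply(calls1, function(d)
    d[, c("peptide_id", "condition", "is_outlier")]))
  u1 <- unique(s1$peptide_id)
  u2 <- unique(calls2$peptide_id)
  if (!length(intersect(u1, u2)))
    stop("the two strategies were run on disjoint peptide sets; ",
         "check the upstream join")
  hit1 <- s1[s1$is_outlier, c("peptide_id", "condition")]
  hit2 <- calls2[calls2$is_significant, c("peptide_id", "condition")]
  peps <- sort(union(hit1$peptide_id, hit2$peptide_id))
  if (!length(peps))
    return(data.frame(peptide_id = character(),
                      conditions_detected = character(),
                      n_conditions = integer(), by_strategy1 = logical(),
                      by_strategy2 = logical(), confidence = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(peps, function(p) {
    conds <- sort(union(hit1$condition[hit1$peptide_id == p],
                        hit2$condition[hit2$peptide_id == p]))
    b1 <- p %in% hit1$peptide_id
    b2 <- p %in% hit2$peptide_id
    data.frame(peptide_id = p,
               conditions_detected = paste(conds, collapse = ","),
               n_conditions = length(conds),
               by_strategy1 = b1, by_strategy2 = b2,
               confidence = if (b1 && b2 && length(conds) >= 2L) "high"
                            else "candidate",
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$confidence != "high", out$peptide_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
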