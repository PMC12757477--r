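# Proteome-transcriptome fold-change concordance with robust outlier removal.

#' Match differential proteins to their transcripts
#'
#' Pairs each differentially expressed protein with its mapped, measured
#' transcript. Mapping ambiguity (several rows for one protein) is an error,
#' never silently resolved; unmapped proteins and proteins whose gene is
#' absent from the transcript results are counted and reported as
#' attributes.
#'
#' @param deps contrast-result data.frame restricted to the DEPs of
#'   interest (protein ids in \code{feature_id}).
#' @param degs contrast-result data.frame of the transcript contrast (all
#'   measured genes, not only significant ones).
#' @param mapping data.frame (protein_id, gene_id), see [readMapping].
#' @return data.frame (protein_id, gene_id, log2fc_protein, log2fc_rna,
#'   same_direction) with attributes \code{n_unmapped} and
#'   \code{n_unmeasured}. A pair with either fold change exactly zero has
#'   \code{same_direction = FALSE} (zero has no sign).
#' @export
matchFeatures <- function(deps, degs, mapping) {
  if (!nrow(mapping)) stop("empty protein-to-gene mapping")
  dup <- unique(mapping$protein_id[duplicated(mapping$protein_id)])
  if (length(dup))
    stop("ambiguous mapping for protein(s): ", paste(dup, collapse = ", "))
  gene <- stats::setNames(mapping$gene_id, mapping$protein_id)[
    deps$feature_id]
  unmapped <- is.na(gene)
  rna <- stats::setNames(degs$log2fc, degs$feature_id)[gene]
  unmeasured <- !unmapped & is.na(rna)
  keep <- !unmapped & !unmeasured
  pairs <- data.frame(
    protein_id = deps$feature_id[keep],
    gene_id = unname(gene[keep]),
    log2fc_protein = deps$log2fc[keep],
    log2fc_rna = unname(rna[keep]),
    stringsAsFactors = FALSE)
  pairs$same_direction <- sign(pairs$log2fc_protein) ==
    sign(pairs$log2fc_rna) & pairs$log2fc_protein != 0
  attr(pairs, "n_unmapped") <- sum(unmapped)
  attr(pairs, "n_unmeasured") <- sum(unmeasured)
  pairs
}

#' Remove robust outliers and correlate protein and RNA fold changes
#'
#' Modified Z-scores are computed separately on the protein-FC vector and
#' the RNA-FC vector (single pass); a pair is an outlier if either score
#' reaches \code{zConcordance} in magnitude ("outliers in the RNA-Seq or
#' protein data"). Pearson correlation is computed on the survivors.
#'
#' @param pairs data.frame from [matchFeatures].
#' @param th a [Thresholds-class] (default cutoff: modified Z >= 3.5).
#' @return list with \code{r} (Pearson correlation on survivors),
#'   \code{n_kept}, \code{n_removed}, \code{n_same_direction} (among kept)
#'   and \code{pairs} (input annotated with z_protein, z_rna, is_outlier).
#' @export
removeOutliersAndCorrelate <- function(pairs, th = thresholds()) {
  if (nrow(pairs) < 4L)
    stop("need at least 4 matched pairs")
  zp <- modifiedZscore(pairs$log2fc_protein)
  zr <- modifiedZscore(pairs$log2fc_rna)
  out <- abs(zp) >= th@zConcordance | abs(zr) >= th@zConcordance
  if (sum(!out) < 3L)
    stop("insufficient pairs after outlier removal")
  pairs$z_protein <- zp
  pairs$z_rna <- zr
  pairs$is_outlier <- out
  r <- stats::cor(pairs$log2fc_protein[!out], pairs$log2fc_rna[!out])
  list(r = r,
       n_kept = sum(!out),
       n_removed = sum(out),
       n_same_direction = sum(pairs$same_direction[!out]),
       pairs = pairs)
}
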