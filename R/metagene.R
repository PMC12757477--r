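# Metagene analysis of the DEGs shared by every mutant-versus-reference
# comparison: average the per-contrast log2FCs, classify genes into
# gain-of-function vs loss-of-function transcriptional responses, and test
# each subset mean against zero.

.one_sample_t <- function(x) {
  if (length(x) < 3L)
    return(list(p = NA_real_, mean = mean(x), n = length(x),
                note = "subset too small (< 3)"))
  if (stats::var(x) == 0)
    return(list(p = 1, mean = mean(x), n = length(x),
                note = "zero variance"))
  list(p = stats::t.test(x, mu = 0)$p.value, mean = mean(x),
       n = length(x), note = "")
}

#' Classify shared DEGs into gain- and loss-of-function responses
#'
#' For every gene in the shared DEG set, the mutant-versus-reference log2FCs
#' are averaged over the mutant contrasts (unweighted arithmetic mean) and
#' compared with the control-versus-reference log2FC:
#' \itemize{
#'   \item loss of function (LoF): down in mutants versus the reference AND
#'     down in the control versus the reference — the gene is activated by
#'     the reference (wild-type) protein and that activation disappears in
#'     the mutants;
#'   \item gain of function (GoF): up in mutants versus the reference while
#'     the control sits at the reference level (|control log2FC| below the
#'     near-zero band) — activation specific to the mutants;
#'   \item anything else is unclassified.
#' }
#' For the down- and up-regulated subsets separately, one-sample two-sided
#' t-tests compare (a) the per-gene mean mutant log2FCs and (b) the per-gene
#' control log2FCs against 0.
#'
#' @param common_degs character vector of shared DEG ids (from
#'   [intersectDegs]).
#' @param mutant_contrasts named list of contrast-result data.frames, one
#'   per mutant (mutant versus reference).
#' @param control_contrast contrast-result data.frame of control versus
#'   reference (e.g. the no-transgene line versus the wild-type line).
#' @param near_zero_band |control log2FC| below which the control is
#'   considered at reference level; default the package's
#'   not-differentially-expressed bound (0.585).
#' @return list with \code{results} (gene_id, mean_log2fc_mut_vs_ref,
#'   log2fc_control_vs_ref, class), \code{tests} (data.frame of the four
#'   subset t-tests) and \code{long} (one row per gene x contrast, for
#'   violin-style plots).
#' @export
metageneClassify <- function(common_degs, mutant_contrasts, control_contrast,
                             near_zero_band = thresholds()@log2fcMin) {
  if (!length(common_degs)) stop("empty shared DEG set")
  if (length(mutant_contrasts) < 1L) stop("need at least one mutant contrast")
  fcs <- vapply(mutant_contrasts, function(d) {
    v <- stats::setNames(d$log2fc, d$feature_id)[common_degs]
    if (any(is.na(v)))
      stop("gene(s) missing from a mutant contrast: ",
           paste(common_degs[is.na(v)], collapse = ", "))
    v
  }, numeric(length(common_degs)))
  fcs <- matrix(fcs, nrow = length(common_degs),
                dimnames = list(common_degs, names(mutant_contrasts)))
  ctrl <- stats::setNames(control_contrast$log2fc,
                          control_contrast$feature_id)[common_degs]
  if (any(is.na(ctrl)))
    stop("gene(s) missing from the control contrast: ",
         paste(common_degs[is.na(ctrl)], collapse = ", "))
  meanMut <- rowMeans(fcs)
  cls <- rep("unclassified", length(common_degs))
  cls[meanMut < 0 & ctrl < 0] <- "LoF"
  cls[meanMut > 0 & abs(ctrl) < near_zero_band] <- "GoF"
  results <- data.frame(gene_id = common_degs,
                        mean_log2fc_mut_vs_ref = unname(meanMut),
                        log2fc_control_vs_ref = unname(ctrl),
                        class = cls,
                        stringsAsFactors = FALSE, row.names = NULL)

  subsets <- list(down = meanMut < 0, up = meanMut > 0)
  tests <- do.call(rbind, lapply(names(subsets), function(s) {
    sel <- subsets[[s]]
    tm <- .one_sample_t(meanMut[sel])
    tc <- .one_sample_t(ctrl[sel])
    data.frame(subset = s,
               test = c("mutants_vs_reference", "control_vs_reference"),
               n = c(tm$n, tc$n),
               mean_log2fc = c(tm$mean, tc$mean),
               p = c(tm$p, tc$p),
               note = c(tm$note, tc$note),
               stringsAsFactors = FALSE)
  }))
  rownames(tests) <- NULL

  long <- data.frame(
    gene_id = rep(common_degs, times = ncol(fcs)),
    contrast = rep(colnames(fcs), each = nrow(fcs)),
    log2fc = as.vector(fcs),
    stringsAsFactors = FALSE)

  list(results = results, tests = tests, long = long)
}
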