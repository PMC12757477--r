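#' @import methods
NULL

.FEATURE_KINDS <- c("protein", "phosphopeptide", "transcript")

#' Sample design: mapping of samples to conditions and replicates
#'
#' Declares the sample universe of an experiment: each sample belongs to one
#' condition and carries a replicate index. One condition is flagged as the
#' reference of the default contrast (typically the wild-type line against
#' which mutants are compared, or a landing-pad control).
#'
#' @slot sampleId character vector of unique sample identifiers.
#' @slot condition character vector, parallel to \code{sampleId}.
#' @slot replicate integer vector of positive replicate indices.
#' @slot reference single condition name used as default contrast reference.
#'
#' @exportClass SampleDesign
setClass("SampleDesign",
  representation(
    sampleId  = "character",
    condition = "character",
    replicate = "integer",
    reference = "character"
  )
)

setValidity("SampleDesign", function(object) {
  msg <- character()
  n <- length(object@sampleId)
  if (n == 0L)
    msg <- c(msg, "design contains no samples")
  if (length(object@condition) != n || length(object@replicate) != n)
    msg <- c(msg, "sampleId, condition and replicate must have equal length")
  dup <- unique(object@sampleId[duplicated(object@sampleId)])
  if (length(dup))
    msg <- c(msg, paste0("duplicated sample_id: ",
                         paste(dup, collapse = ", ")))
  if (any(!is.na(object@replicate) & object@replicate < 1L))
    msg <- c(msg, "replicate indices must be positive")
  if (length(object@reference) != 1L)
    msg <- c(msg, "exactly one reference condition must be flagged")
  else if (n > 0L && !(object@reference %in% object@condition))
    msg <- c(msg, paste0("reference condition '", object@reference,
                         "' has no samples"))
  if (length(msg)) msg else TRUE
})

#' Construct a SampleDesign
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param condition character vector of condition labels, one per sample.
#' @param replicate integer replicate indices, one per sample.
#' @param reference the reference condition of the default contrast; defaults
#'   to the first condition encountered.
#' @return A [SampleDesign-class] object.
#' @examples
#' sampleDesign(c("LP_r1", "LP_r2", "WT_r1", "WT_r2"),
#'              c("LP", "LP", "WT", "WT"), c(1, 2, 1, 2), reference = "WT")
#' @export
sampleDesign <- function(sample_id, condition, replicate,
                         reference = condition[1L]) {
  new("SampleDesign",
      sampleId  = as.character(sample_id),
      condition = as.character(condition),
      replicate = as.integer(replicate),
      reference = as.character(reference))
}

#' Feature-by-sample abundance table
#'
#' Non-negative abundance matrix (label-free protein intensities,
#' phosphopeptide intensities or transcript expression values) with explicit
#' missingness: \code{NA} means not quantified, which is distinct from zero.
#'
#' @slot values numeric matrix, rows = features, columns = samples; entries
#'   are \code{NA} (missing) or \eqn{\ge 0}.
#' @slot kind one of \code{"protein"}, \code{"phosphopeptide"},
#'   \code{"transcript"}.
#'
#' @exportClass AbundanceTable
setClass("AbundanceTable",
  representation(values = "matrix", kind = "character")
)

setValidity("AbundanceTable", function(object) {
  msg <- character()
  v <- object@values
  if (!is.numeric(v))
    msg <- c(msg, "values must be a numeric matrix")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "values must carry feature and sample names")
  else {
    if (anyDuplicated(rownames(v)))
      msg <- c(msg, "feature_ids must be unique")
    if (anyDuplicated(colnames(v)))
      msg <- c(msg, "sample_ids must be unique")
  }
  if (is.numeric(v) && any(v < 0, na.rm = TRUE)) {
    bad <- which(v < 0, arr.ind = TRUE)[1L, ]
    msg <- c(msg, sprintf("negative abundance at (%s, %s)",
                          rownames(v)[bad[1L]], colnames(v)[bad[2L]]))
  }
  if (length(object@kind) != 1L || !(object@kind %in% .FEATURE_KINDS))
    msg <- c(msg, paste0("kind must be one of: ",
                         paste(.FEATURE_KINDS, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct an AbundanceTable
#'
#' @param values numeric matrix with feature rownames and sample colnames;
#'   \code{NA} marks missing (not quantified) entries.
#' @param kind feature kind: \code{"protein"}, \code{"phosphopeptide"} or
#'   \code{"transcript"}.
#' @return An [AbundanceTable-class].
#' @export
abundanceTable <- function(values, kind) {
  new("AbundanceTable", values = values, kind = kind)
}

#' Phosphopeptide abundances normalized to parent-protein level
#'
#' An [AbundanceTable-class] of per-sample ratios
#' phosphopeptide / parent protein, together with the peptide-to-parent map.
#' An entry is present only where both the peptide and its parent protein
#' were quantified in that sample.
#'
#' @slot parent named character vector: parent protein id per peptide id.
#'
#' @exportClass NormalizedPhosphoTable
setClass("NormalizedPhosphoTable",
  contains = "AbundanceTable",
  representation(parent = "character")
)

setValidity("NormalizedPhosphoTable", function(object) {
  msg <- character()
  if (!identical(sort(names(object@parent)), sort(rownames(object@values))))
    msg <- c(msg, "parent map must name exactly the peptides in the table")
  if (length(msg)) msg else TRUE
})

#' Analysis thresholds
#'
#' All cutoffs used across the pipeline, with defaults reproducing the
#' published settings: BH-adjusted p < 0.05, |log2FC| >= 0.585 (fold change
#' 1.5), modified Z >= 1 for differential-phosphorylation outliers, modified
#' Z >= 3.5 for concordance outlier removal, ptmRS localization score > 50,
#' and a pseudocount of 1 added to abundance ratios before log2.
#'
#' @slot alphaAdj adjusted-p significance level (default 0.05).
#' @slot log2fcMin minimum |log2 fold change| (default 0.585, i.e. FC 1.5).
#' @slot zDphospho modified-Z cutoff for strategy-1 outliers (default 1).
#' @slot zConcordance modified-Z cutoff for concordance outliers (default 3.5).
#' @slot ptmrsMin ptmRS score that must be strictly exceeded (default 50).
#' @slot pseudocountRatio pseudocount added to each abundance ratio before
#'   taking log2 (default 1).
#' @slot pseudocountAbund pseudocount added to group means before log ratios;
#'   \code{NA} (default) means half the smallest positive value in the table.
#'
#' @exportClass Thresholds
setClass("Thresholds",
  representation(
    alphaAdj = "numeric", log2fcMin = "numeric", zDphospho = "numeric",
    zConcordance = "numeric", ptmrsMin = "numeric",
    pseudocountRatio = "numeric", pseudocountAbund = "numeric"
  ),
  prototype(
    alphaAdj = 0.05, log2fcMin = 0.585, zDphospho = 1,
    zConcordance = 3.5, ptmrsMin = 50,
    pseudocountRatio = 1, pseudocountAbund = NA_real_
  )
)

setValidity("Thresholds", function(object) {
  vals <- c(alphaAdj = object@alphaAdj, log2fcMin = object@log2fcMin,
            zDphospho = object@zDphospho, zConcordance = object@zConcordance,
            ptmrsMin = object@ptmrsMin,
            pseudocountRatio = object@pseudocountRatio)
  bad <- names(vals)[!is.finite(vals) | vals <= 0]
  if (length(bad))
    return(paste0("thresholds must be strictly positive: ",
                  paste(bad, collapse = ", ")))
  if (!is.na(object@pseudocountAbund) && object@pseudocountAbund <= 0)
    return("pseudocountAbund must be positive (or NA for data-driven)")
  TRUE
})

#' Construct a Thresholds object
#'
#' @param alphaAdj,log2fcMin,zDphospho,zConcordance,ptmrsMin,pseudocountRatio,pseudocountAbund
#'   see [Thresholds-class]; defaults reproduce the published settings.
#' @return A [Thresholds-class].
#' @examples
#' thresholds()                  # published defaults
#' thresholds(zDphospho = 3.5)   # stricter outlier cutoff
#' @export
thresholds <- function(alphaAdj = 0.05, log2fcMin = 0.585, zDphospho = 1,
                       zConcordance = 3.5, ptmrsMin = 50,
                       pseudocountRatio = 1, pseudocountAbund = NA_real_) {
  new("Thresholds", alphaAdj = alphaAdj, log2fcMin = log2fcMin,
      zDphospho = zDphospho, zConcordance = zConcordance,
      ptmrsMin = ptmrsMin, pseudocountRatio = pseudocountRatio,
      pseudocountAbund = pseudocountAbund)
}

#' Configuration of the synthetic-data generator
#'
#' Defines the simulated study: seven fly lines (landing-pad control LP,
#' WT AKT1, four hyperactive mutants T1/T5/T12/T15 and the Q79K-W80R double
#' mutant), three replicates per condition with a fourth WT replicate for the
#' MS tables, log-normal baseline abundances, and planted effects for every
#' signal the downstream analyses are designed to detect.
#'
#' @slot nProteins,nTranscripts,nPhospho feature counts per table.
#' @slot conditions condition labels; the first is the no-transgene control,
#'   the second the wild-type reference, the rest mutants.
#' @slot replicates replicates per condition (transcriptome and default).
#' @slot wtProteinReplicates replicates of the reference condition in the MS
#'   (protein and phosphopeptide) tables.
#' @slot fracDep,fracDeg fraction of proteins/transcripts planted as
#'   differentially expressed in mutants versus the reference.
#' @slot fracDphospho fraction of phosphopeptides planted with a
#'   phosphorylation change independent of their parent protein.
#' @slot effectLog2 planted effect size on the log2 scale.
#' @slot cvNoise coefficient of variation of multiplicative replicate noise.
#' @slot fracConcordant fraction of planted DEPs whose mapped transcript is
#'   planted as a DEG in the same direction.
#' @slot nGof,nLof numbers of gain-of-function / loss-of-function genes.
#' @slot nTfs number of transcription factors in the TF-target graph.
#' @slot missingRate completely-at-random missingness rate (default 0).
#' @slot seed integer RNG seed (required; same config implies identical
#'   output).
#'
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(
    nProteins = "integer", nTranscripts = "integer", nPhospho = "integer",
    conditions = "character", replicates = "integer",
    wtProteinReplicates = "integer",
    fracDep = "numeric", fracDeg = "numeric", fracDphospho = "numeric",
    effectLog2 = "numeric", cvNoise = "numeric", fracConcordant = "numeric",
    nGof = "integer", nLof = "integer", nTfs = "integer",
    missingRate = "numeric", seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  fr <- c(fracDep = object@fracDep, fracDeg = object@fracDeg,
          fracDphospho = object@fracDphospho,
          fracConcordant = object@fracConcordant,
          missingRate = object@missingRate)
  bad <- names(fr)[fr < 0 | fr > 1]
  if (length(bad))
    msg <- c(msg, paste0("fractions must lie in [0,1]: ",
                         paste(bad, collapse = ", ")))
  if (length(object@conditions) < 3L)
    msg <- c(msg, "need a control, a reference and at least one mutant")
  if (anyDuplicated(object@conditions))
    msg <- c(msg, "conditions must be unique")
  if (object@replicates < 2L || object@wtProteinReplicates < 2L)
    msg <- c(msg, "every tested condition needs at least 2 replicates")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "seed is required")
  if (object@nGof + object@nLof + ceiling(object@fracDeg *
        object@nTranscripts) > object@nTranscripts)
    msg <- c(msg, "planted gene groups exceed the transcript universe")
  if (length(msg)) msg else TRUE
})

#' Construct a SimulationConfig
#'
#' @param seed integer RNG seed (required).
#' @param nProteins,nTranscripts,nPhospho,conditions,replicates,wtProteinReplicates,fracDep,fracDeg,fracDphospho,effectLog2,cvNoise,fracConcordant,nGof,nLof,nTfs,missingRate
#'   see [SimulationConfig-class].
#' @return A [SimulationConfig-class].
#' @examples
#' cfg <- simulationConfig(seed = 1)
#' cfg
#' @export
simulationConfig <- function(seed,
                             nProteins = 2000L, nTranscripts = 5000L,
                             nPhospho = 60L,
                             conditions = c("LP", "WT", "T1", "T5", "T12",
                                            "T15", "Q79KW80R"),
                             replicates = 3L, wtProteinReplicates = 4L,
                             fracDep = 0.1, fracDeg = 0.1,
                             fracDphospho = 0.25, effectLog2 = 2.0,
                             cvNoise = 0.2, fracConcordant = 0.2,
                             nGof = 40L, nLof = 40L, nTfs = 29L,
                             missingRate = 0) {
  new("SimulationConfig",
      nProteins = as.integer(nProteins),
      nTranscripts = as.integer(nTranscripts),
      nPhospho = as.integer(nPhospho),
      conditions = as.character(conditions),
      replicates = as.integer(replicates),
      wtProteinReplicates = as.integer(wtProteinReplicates),
      fracDep = fracDep, fracDeg = fracDeg, fracDphospho = fracDphospho,
      effectLog2 = effectLog2, cvNoise = cvNoise,
      fracConcordant = fracConcordant,
      nGof = as.integer(nGof), nLof = as.integer(nLof),
      nTfs = as.integer(nTfs), missingRate = missingRate,
      seed = as.integer(seed))
}

#' Ground truth of a simulated dataset
#'
#' Ledger of every planted effect, used by recovery tests to score the
#' pipeline's calls.
#'
#' @slot depIds,depDirections planted differential proteins and their signs.
#' @slot degIds,degDirections planted differential genes (mutants versus
#'   reference) and their signs.
#' @slot dphosphoIds peptides with a planted protein-independent
#'   phosphorylation change; \code{dphosphoDirections} their signs.
#' @slot dphosphoDirections named numeric of planted phospho effect signs.
#' @slot gofGeneIds,lofGeneIds gain- / loss-of-function gene subsets.
#' @slot concordantPairs data.frame (protein_id, gene_id) of DEPs whose
#'   transcript was planted in the same direction.
#' @slot tfModules named character: planted module ("down"/"up"/"background")
#'   per TF.
#' @slot geneModules named character: planted module per clustered gene.
#' @slot hubNode designated maximum-degree node of the PPI graph.
#'
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(
    depIds = "character", depDirections = "numeric",
    degIds = "character", degDirections = "numeric",
    dphosphoIds = "character", dphosphoDirections = "numeric",
    gofGeneIds = "character", lofGeneIds = "character",
    concordantPairs = "data.frame",
    tfModules = "character", geneModules = "character",
    hubNode = "character"
  )
)

setValidity("GroundTruth", function(object) {
  msg <- character()
  if (length(intersect(object@gofGeneIds, object@lofGeneIds)))
    msg <- c(msg, "gain- and loss-of-function gene sets must be disjoint")
  if (length(msg)) msg else TRUE
})
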