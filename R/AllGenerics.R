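#' Accessors for pipeline data objects
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x a [SampleDesign-class], [AbundanceTable-class] or related object.
#' @return `sampleIds`: character vector of sample identifiers.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @rdname accessors
#' @export
setGeneric("conditions", function(x) standardGeneric("conditions"))

#' @rdname accessors
#' @export
setGeneric("referenceCondition",
           function(x) standardGeneric("referenceCondition"))

#' @rdname accessors
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))

#' @rdname accessors
#' @export
setGeneric("featureKind", function(x) standardGeneric("featureKind"))

#' @rdname accessors
#' @export
setGeneric("parentProteins", function(x) standardGeneric("parentProteins"))

#' Samples belonging to a condition
#'
#' @param x a [SampleDesign-class].
#' @param condition one or more condition labels.
#' @return character vector of sample ids in those conditions.
#' @export
setGeneric("samplesFor", function(x, condition) standardGeneric("samplesFor"))

#' @rdname accessors
setMethod("sampleIds", "SampleDesign", function(x) x@sampleId)

#' @rdname accessors
setMethod("conditions", "SampleDesign", function(x) unique(x@condition))

#' @rdname accessors
setMethod("referenceCondition", "SampleDesign", function(x) x@reference)

#' @describeIn samplesFor sample ids of a condition, in design order
setMethod("samplesFor", "SampleDesign", function(x, condition) {
  unknown <- setdiff(condition, x@condition)
  if (length(unknown))
    stop("unknown condition(s): ", paste(unknown, collapse = ", "))
  x@sampleId[x@condition %in% condition]
})

#' @rdname accessors
setMethod("sampleIds", "AbundanceTable", function(x) colnames(x@values))

#' @rdname accessors
setMethod("featureIds", "AbundanceTable", function(x) rownames(x@values))

#' @rdname accessors
setMethod("abundances", "AbundanceTable", function(x) x@values)

#' @rdname accessors
setMethod("featureKind", "AbundanceTable", function(x) x@kind)

#' @rdname accessors
setMethod("parentProteins", "NormalizedPhosphoTable",
          function(x) x@parent[rownames(x@values)])

setMethod("show", "SampleDesign", function(object) {
  tab <- table(object@condition)
  cat(sprintf("SampleDesign with %d samples in %d conditions (reference: %s)\n",
              length(object@sampleId), length(tab), object@reference))
  cat(paste0("  ", names(tab), ": n=", as.integer(tab), collapse = "\n"),
      "\n")
})

setMethod("show", "AbundanceTable", function(object) {
  v <- object@values
  cat(sprintf("AbundanceTable [%s]: %d features x %d samples (%.1f%% missing)\n",
              object@kind, nrow(v), ncol(v), 100 * mean(is.na(v))))
})

setMethod("show", "NormalizedPhosphoTable", function(object) {
  v <- object@values
  cat(sprintf(
    "NormalizedPhosphoTable: %d peptides x %d samples (%.1f%% missing)\n",
    nrow(v), ncol(v), 100 * mean(is.na(v))))
})

setMethod("show", "Thresholds", function(object) {
  cat("Thresholds:\n",
      sprintf("  adjusted p < %g; |log2FC| >= %g (FC %.2f)\n",
              object@alphaAdj, object@log2fcMin, 2^object@log2fcMin),
      sprintf("  modified Z: dphospho >= %g, concordance >= %g\n",
              object@zDphospho, object@zConcordance),
      sprintf("  ptmRS > %g; ratio pseudocount %g\n",
              object@ptmrsMin, object@pseudocountRatio))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig (seed %d): %d proteins, %d transcripts, %d phosphopeptides\n",
    object@seed, object@nProteins, object@nTranscripts, object@nPhospho))
  cat(sprintf(
    "  conditions: %s; reps %d (reference %d for MS); effect %.2g log2, cv %.2g\n",
    paste(object@conditions, collapse = ", "), object@replicates,
    object@wtProteinReplicates, object@effectLog2, object@cvNoise))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf(
    "GroundTruth: %d DEPs, %d DEGs, %d DPhospho, %d GoF, %d LoF genes; hub %s\n",
    length(object@depIds), length(object@degIds), length(object@dphosphoIds),
    length(object@gofGeneIds), length(object@lofGeneIds), object@hubNode))
})
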