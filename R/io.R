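# Readers/writers for the plain-text formats the pipeline touches.
# Everything is tab-separated UTF-8 with a header row; "NA" and the empty
# string both mean missing. Floating point is written at 12 significant
# digits so round-trips are reproducible to the digits shown.

.read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) stop("format error: empty file: ", path)
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    na.strings = c("NA", ""), stringsAsFactors = FALSE,
                    quote = "", comment.char = "")
}

.write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1L)) &
         !vapply(df, is.integer, logical(1L))
  df[num] <- lapply(df[num], function(x) {
    out <- formatC(x, digits = 12L, format = "g")
    out[is.na(x)] <- NA
    out
  })
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
}

.require_columns <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("format error in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
}

#' Read a sample-design table
#'
#' Tab-separated file with header columns \code{sample_id}, \code{condition},
#' \code{replicate} and optionally \code{reference} (logical or 0/1 flag on
#' the reference condition's rows).
#'
#' @param path file path.
#' @param reference reference condition; if \code{NULL}, taken from a
#'   \code{reference} column when present, else the first condition.
#' @return A [SampleDesign-class].
#' @export
readSampleDesign <- function(path, reference = NULL) {
  df <- .read_tsv(path)
  .require_columns(df, c("sample_id", "condition", "replicate"), path)
  if (is.null(reference)) {
    reference <- if ("reference" %in% names(df)) {
      ref <- unique(df$condition[as.logical(df$reference) %in% TRUE])
      if (length(ref) != 1L)
        stop("validation error: exactly one condition must be flagged as ",
             "reference, found ", length(ref))
      ref
    } else df$condition[1L]
  }
  sampleDesign(df$sample_id, df$condition, df$replicate,
               reference = reference)
}

#' Write a sample-design table
#'
#' @param design a [SampleDesign-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSampleDesign <- function(design, path) {
  df <- data.frame(sample_id = design@sampleId,
                   condition = design@condition,
                   replicate = design@replicate,
                   reference = design@condition == design@reference)
  .write_tsv(df, path)
  invisible(path)
}

#' Read a feature-by-sample abundance table
#'
#' First column is the feature identifier, remaining columns are per-sample
#' abundances. Blank and "NA" cells are missing (distinct from zero); any
#' negative value is rejected.
#'
#' @param path file path.
#' @param kind feature kind: \code{"protein"}, \code{"phosphopeptide"} or
#'   \code{"transcript"}.
#' @return An [AbundanceTable-class].
#' @export
readAbundanceTable <- function(path, kind) {
  df <- .read_tsv(path)
  if (ncol(df) < 2L)
    stop("format error in ", path, ": need a feature_id column plus samples")
  ids <- as.character(df[[1L]])
  vals <- df[-1L]
  # a column that is entirely missing is read as logical; it is still numeric
  allNA <- vapply(vals, function(x) is.logical(x) && all(is.na(x)),
                  logical(1L))
  vals[allNA] <- lapply(vals[allNA], as.numeric)
  bad_col <- names(vals)[!vapply(vals, is.numeric, logical(1L))]
  if (length(bad_col))
    stop("format error in ", path, ": non-numeric cells in column(s) ",
         paste(bad_col, collapse = ", "))
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (anyDuplicated(ids))
    stop("validation error: duplicated feature_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(m < 0, na.rm = TRUE)) {
    bad <- which(m < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("validation error: negative abundance at (%s, %s)",
                 ids[bad[1L]], colnames(m)[bad[2L]]))
  }
  abundanceTable(m, kind)
}

#' Write an abundance table
#'
#' @param table an [AbundanceTable-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAbundanceTable <- function(table, path) {
  m <- abundances(table)
  df <- data.frame(feature_id = rownames(m), as.data.frame(m),
                   check.names = FALSE)
  .write_tsv(df, path)
  invisible(path)
}

.DIRECTIONS <- c("up", "down", "unchanged")

#' Validate a contrast-result data.frame
#'
#' A contrast result carries, per feature, the log2 fold change of a test
#' condition over a reference, raw and BH-adjusted p-values and a direction
#' call.
#'
#' @param results data.frame with columns \code{feature_id}, \code{log2fc},
#'   \code{p_raw}, \code{p_adj}, \code{direction}.
#' @return the validated data.frame, invisibly.
#' @export
validateContrastResult <- function(results) {
  .require_columns(results,
                   c("feature_id", "log2fc", "p_raw", "p_adj", "direction"),
                   "contrast result")
  if (anyDuplicated(results$feature_id))
    stop("validation error: duplicated feature_id in contrast result")
  ok <- !is.na(results$p_raw) & !is.na(results$p_adj)
  if (any(results$p_adj[ok] < results$p_raw[ok] - 1e-12))
    stop("validation error: p_adj < p_raw")
  if (any(!results$direction %in% .DIRECTIONS))
    stop("validation error: direction must be up/down/unchanged")
  bad <- results$direction == "up" & results$log2fc < 0 |
         results$direction == "down" & results$log2fc > 0
  if (any(bad, na.rm = TRUE))
    stop("validation error: direction inconsistent with sign of log2fc")
  invisible(results)
}

#' Write a contrast-result table
#'
#' Columns are written in the fixed order feature_id, log2fc, p_raw, p_adj,
#' direction; numeric values at 12 significant digits so that
#' \code{readContrastResult(writeContrastResult(x)) == x} to the digits
#' shown.
#'
#' @param results contrast-result data.frame (see [validateContrastResult]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeContrastResult <- function(results, path) {
  if (!is.data.frame(results) || nrow(results) == 0L)
    stop("refusing to write an empty contrast result")
  validateContrastResult(results)
  .write_tsv(results[, c("feature_id", "log2fc", "p_raw", "p_adj",
                         "direction")], path)
  invisible(path)
}

#' Read a contrast-result table
#'
#' Accepts tables written by [writeContrastResult] as well as upstream
#' differential-expression exports with the same columns (e.g. a gene,
#' log2FC, p, adjusted-p table from an RNA-Seq DE tool).
#'
#' @param path file path.
#' @return validated contrast-result data.frame.
#' @export
readContrastResult <- function(path) {
  df <- .read_tsv(path)
  .require_columns(df, c("feature_id", "log2fc", "p_raw", "p_adj"), path)
  if (!"direction" %in% names(df))
    df$direction <- ifelse(df$log2fc > 0, "up",
                           ifelse(df$log2fc < 0, "down", "unchanged"))
  validateContrastResult(df)
  df
}

#' Read a gene-set collection in GMT format
#'
#' Standard GMT: one set per line, \code{name TAB description TAB member...}.
#'
#' @param path file path.
#' @param source_db label recorded as the collection source.
#' @return named list of character vectors, with a \code{source_db} attribute
#'   (one label per set).
#' @export
readGmt <- function(path, source_db = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("format error: empty GMT file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(parts, length, integer(1L)) < 3L
  if (any(short))
    stop("format error in ", path, ": GMT lines need name, description and ",
         "at least one member (line ", which(short)[1L], ")")
  sets <- lapply(parts, function(p) unique(p[-c(1L, 2L)]))
  names(sets) <- vapply(parts, `[[`, character(1L), 1L)
  if (anyDuplicated(names(sets)))
    stop("validation error: duplicated set names in ", path)
  attr(sets, "description") <- vapply(parts, `[[`, character(1L), 2L)
  attr(sets, "source_db") <- rep(source_db, length.out = length(sets))
  sets
}

#' Write a gene-set collection in GMT format
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description one description per set (recycled).
#' @return `path`, invisibly.
#' @export
writeGmt <- function(sets, path, description = "na") {
  description <- rep(description, length.out = length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a two-column edge list
#'
#' Used for TF-to-target annotations and PPI graphs. An optional third
#' numeric column (e.g. an interaction confidence score) is kept when
#' present.
#'
#' @param path file path.
#' @param from,to expected names of the first two columns; if the file's
#'   header differs, the first two columns are used positionally.
#' @return data.frame with columns `from`, `to` (and `score` if present).
#' @export
readEdgeList <- function(path, from = "from", to = "to") {
  df <- .read_tsv(path)
  if (ncol(df) < 2L)
    stop("format error in ", path, ": an edge list needs two columns")
  out <- data.frame(from = as.character(df[[1L]]),
                    to = as.character(df[[2L]]),
                    stringsAsFactors = FALSE)
  if (ncol(df) >= 3L && is.numeric(df[[3L]])) out$score <- df[[3L]]
  out[stats::complete.cases(out[, c("from", "to")]), , drop = FALSE]
}

#' Write a two-column edge list
#'
#' @param edges data.frame whose first two columns are node identifiers.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(edges, path) {
  .write_tsv(edges, path)
  invisible(path)
}

#' Read a protein-to-gene mapping table
#'
#' Two-column TSV (protein_id, gene_id). Feature identifiers are opaque,
#' case-sensitive strings: matching MS proteins to RNA-Seq genes always goes
#' through such an explicit mapping, never through identifier munging.
#'
#' @param path file path.
#' @return data.frame with columns `protein_id`, `gene_id`.
#' @export
readMapping <- function(path) {
  df <- .read_tsv(path)
  if (ncol(df) < 2L)
    stop("format error in ", path, ": mapping needs two columns")
  data.frame(protein_id = as.character(df[[1L]]),
             gene_id = as.character(df[[2L]]),
             stringsAsFactors = FALSE)
}

#' Read phosphopeptide records
#'
#' TSV with columns \code{peptide_id}, \code{parent_protein_id},
#' \code{site_descriptor}, \code{ptmrs_score}.
#'
#' @param path file path.
#' @return data.frame of phosphopeptide records.
#' @export
readPhosphoRecords <- function(path) {
  df <- .read_tsv(path)
  .require_columns(df, c("peptide_id", "parent_protein_id", "site_descriptor",
                         "ptmrs_score"), path)
  if (any(is.na(df$ptmrs_score)))
    stop("validation error: ptmrs_score must be present for every record")
  if (any(df$ptmrs_score < 0 | df$ptmrs_score > 100))
    stop("validation error: ptmrs_score must lie in [0, 100]")
  df
}
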