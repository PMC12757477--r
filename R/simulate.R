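# Synthetic paired-omics generator with planted ground truth.
#
# The generator emulates the structure of a follicle-cell AKT1 study: seven
# fly lines (LP control, WT reference, five hyperactive mutants), label-free
# MS protein and phosphopeptide tables (4 WT replicates, 3 elsewhere), an
# RNA-Seq-like transcript table (3 replicates everywhere), a TF-target edge
# list with two planted co-regulated modules, a PPI edge list with a
# designated hub, and GMT gene sets. Every stochastic draw is keyed to the
# config seed in a fixed order, so an identical config gives bit-identical
# output.

.sim_sd_log2 <- function(cv) sqrt(log(1 + cv^2)) / log(2)

#' Simulate a complete paired-omics dataset with known ground truth
#'
#' Baseline abundances are log-normal (log2 mean 20, sd 2); replicate noise
#' is multiplicative Gaussian on the log2 scale with the configured
#' coefficient of variation. Planted signals:
#' \itemize{
#'   \item DEPs/DEGs shifted by \eqn{\pm}\code{effectLog2} in all mutant
#'     conditions relative to the reference;
#'   \item differentially phosphorylated peptides whose abundance is shifted
#'     while their parent protein is not (the independence both calling
#'     strategies exploit); all other phosphopeptides track their parent
#'     protein (parent abundance times a site-stoichiometry factor, up to
#'     noise), so protein-level normalization is exactly the right inverse;
#'   \item a configurable fraction of planted DEPs whose mapped transcript is
#'     a DEG in the same direction (mRNA-protein concordance);
#'   \item loss-of-function genes (up in the reference only, so they read as
#'     down in mutants-vs-reference and down in control-vs-reference) and
#'     gain-of-function genes (up in mutants only);
#'   \item a TF-target graph whose two modules target the down- and
#'     up-regulated gene groups, and a PPI graph with one maximal-degree hub.
#' }
#'
#' @param config a [SimulationConfig-class].
#' @return a named list (the dataset bundle) with elements \code{design},
#'   \code{proteins}, \code{phospho}, \code{transcripts} (the three
#'   [AbundanceTable-class]s), \code{phosphoRecords} (peptide records with
#'   ptmRS scores), \code{mapping} (protein-to-gene), \code{tfEdges},
#'   \code{ppiEdges}, \code{geneSets}, \code{truth}
#'   (a [GroundTruth-class]) and \code{config}.
#' @examples
#' bundle <- simulateDataset(simulationConfig(seed = 1, nProteins = 100,
#'   nTranscripts = 250, nPhospho = 20, nGof = 8, nLof = 8, nTfs = 9))
#' bundle$truth
#' @export
simulateDataset <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  set.seed(config@seed)

  conds <- config@conditions
  ctrl <- conds[1L]
  ref <- conds[2L]
  muts <- conds[-c(1L, 2L)]
  sdLog2 <- .sim_sd_log2(config@cvNoise)
  eff <- config@effectLog2

  ## --- sample universe -----------------------------------------------------
  msReps <- ifelse(conds == ref, config@wtProteinReplicates,
                   config@replicates)
  msSamples <- unlist(lapply(seq_along(conds), function(i)
    sprintf("%s_r%d", conds[i], seq_len(msReps[i]))))
  msCond <- rep(conds, msReps)
  msRepIdx <- unlist(lapply(msReps, seq_len))
  design <- sampleDesign(msSamples, msCond, msRepIdx, reference = ref)
  rnaKeep <- msRepIdx <= config@replicates
  rnaSamples <- msSamples[rnaKeep]
  rnaCond <- msCond[rnaKeep]

  nP <- config@nProteins
  nT <- config@nTranscripts
  nPep <- config@nPhospho
  protIds <- sprintf("P%05d", seq_len(nP))
  geneIds <- sprintf("G%05d", seq_len(nT))

  ## --- planted effects (log2 offsets per feature x condition) --------------
  baseP <- stats::rnorm(nP, 20, 2)
  nDep <- round(config@fracDep * nP)
  depIdx <- sort(sample.int(nP, nDep))
  depDir <- sample(c(-1, 1), nDep, replace = TRUE)
  # effect magnitudes spread continuously around effectLog2: real fold-change
  # distributions are continuous, and point-mass effects would make
  # median/MAD-based outlier statistics degenerate downstream
  mag <- function(n) eff * stats::runif(n, 0.6, 1.4)
  depMag <- mag(nDep)

  baseT <- stats::rnorm(nT, 20, 2)
  mappedDep <- depIdx[depIdx <= nT]
  nConc <- min(round(config@fracConcordant * nDep), length(mappedDep))
  concIdx <- if (nConc > 0L) sort(sample(mappedDep, nConc)) else integer()
  concDir <- depDir[match(concIdx, depIdx)]

  # gene pool for groups not tied to proteins: prefer unmapped gene space
  used <- concIdx
  pool <- setdiff(seq_len(nT), c(seq_len(min(nP, nT)), used))
  if (length(pool) < config@nGof + config@nLof)
    pool <- setdiff(seq_len(nT), c(mappedDep, used))
  gofIdx <- sort(sample(pool, config@nGof))
  lofIdx <- sort(sample(setdiff(pool, gofIdx), config@nLof))
  nDegTotal <- round(config@fracDeg * nT)
  nExtra <- max(0L, nDegTotal - config@nGof - config@nLof - nConc)
  extraPool <- setdiff(pool, c(gofIdx, lofIdx))
  nExtra <- min(nExtra, length(extraPool))
  extraIdx <- if (nExtra > 0L) sort(sample(extraPool, nExtra)) else integer()
  extraDir <- sample(c(-1, 1), length(extraIdx), replace = TRUE)

  effP <- matrix(0, nP, length(conds), dimnames = list(protIds, conds))
  if (nDep > 0L)
    effP[depIdx, muts] <- depDir * depMag
  effT <- matrix(0, nT, length(conds), dimnames = list(geneIds, conds))
  if (length(gofIdx)) effT[gofIdx, muts] <- mag(length(gofIdx))
  if (length(lofIdx)) effT[lofIdx, ref] <- mag(length(lofIdx))
  # a concordant transcript mirrors its protein's effect (same direction and
  # size), emulating proportional transcription-driven regulation
  if (length(concIdx))
    effT[concIdx, muts] <- concDir * depMag[match(concIdx, depIdx)]
  if (length(extraIdx)) effT[extraIdx, muts] <- extraDir * mag(length(extraIdx))

  degIdx <- sort(c(gofIdx, lofIdx, concIdx, extraIdx))
  degDir <- numeric(length(degIdx))
  degDir[match(gofIdx, degIdx)] <- 1
  degDir[match(lofIdx, degIdx)] <- -1
  degDir[match(concIdx, degIdx)] <- concDir
  degDir[match(extraIdx, degIdx)] <- extraDir

  ## --- abundance matrices --------------------------------------------------
  protMat <- 2^(baseP + effP[, msCond, drop = FALSE] +
                matrix(stats::rnorm(nP * length(msSamples), 0, sdLog2),
                       nP, length(msSamples)))
  dimnames(protMat) <- list(protIds, msSamples)

  tranMat <- 2^(baseT + effT[, rnaCond, drop = FALSE] +
                matrix(stats::rnorm(nT * length(rnaSamples), 0, sdLog2),
                       nT, length(rnaSamples)))
  dimnames(tranMat) <- list(geneIds, rnaSamples)

  ## --- phosphopeptides ------------------------------------------------------
  nPlant <- round(config@fracDphospho * nPep)
  plantIdx <- if (nPlant > 0L) sort(sample.int(nPep, nPlant)) else integer()
  plantDir <- sample(c(-1, 1), length(plantIdx), replace = TRUE)
  nonDep <- setdiff(seq_len(nP), depIdx)
  parents <- integer(nPep)
  if (length(plantIdx))
    parents[plantIdx] <- sample(nonDep, length(plantIdx),
                                replace = length(nonDep) < length(plantIdx))
  nullIdx <- setdiff(seq_len(nPep), plantIdx)
  # detected phosphopeptides come preferentially from DE parent proteins so
  # the expression/phosphorylation scatter spans a range of expression FCs
  nullPool <- if (length(depIdx) >= length(nullIdx)) depIdx else seq_len(nP)
  parents[nullIdx] <- sample(nullPool, length(nullIdx),
                             replace = length(nullPool) < length(nullIdx))
  stoich <- stats::runif(nPep, -4, -1)
  effPep <- matrix(0, nPep, length(conds), dimnames = list(NULL, conds))
  if (length(plantIdx))
    effPep[plantIdx, muts] <- plantDir * mag(length(plantIdx))
  phosMat <- protMat[parents, , drop = FALSE] *
    2^(stoich + effPep[, msCond, drop = FALSE] +
       matrix(stats::rnorm(nPep * length(msSamples), 0, sdLog2),
              nPep, length(msSamples)))
  pepIds <- sprintf("pep%03d", seq_len(nPep))
  dimnames(phosMat) <- list(pepIds, msSamples)
  sites <- sprintf("S%d", sample(20:800, nPep, replace = TRUE))
  ptmrs <- stats::runif(nPep, 55, 95)

  ## --- missingness (completely at random) ----------------------------------
  if (config@missingRate > 0) {
    drop_cells <- function(m) {
      m[stats::runif(length(m)) < config@missingRate] <- NA
      m
    }
    protMat <- drop_cells(protMat)
    tranMat <- drop_cells(tranMat)
    phosMat <- drop_cells(phosMat)
  }

  ## --- TF-target graph with two planted modules ----------------------------
  degIds <- geneIds[degIdx]
  tfPool <- setdiff(seq_len(nT), degIdx)
  tfIdx <- sort(sample(tfPool, config@nTfs))
  tfIds <- geneIds[tfIdx]
  nMod <- max(1L, config@nTfs %/% 3L)
  tfModule <- rep("background", config@nTfs)
  tfModule[seq_len(nMod)] <- "down"
  tfModule[seq_len(nMod) + nMod] <- "up"
  names(tfModule) <- tfIds
  downGenes <- geneIds[lofIdx]
  upGenes <- geneIds[gofIdx]
  draw_edges <- function(tfs, targets, p) {
    if (!length(tfs) || !length(targets)) return(NULL)
    hit <- matrix(stats::runif(length(tfs) * length(targets)) < p,
                  length(tfs), length(targets))
    idx <- which(hit, arr.ind = TRUE)
    if (!nrow(idx)) return(NULL)
    data.frame(tf = tfs[idx[, 1L]], target = targets[idx[, 2L]],
               stringsAsFactors = FALSE)
  }
  otherDegs <- setdiff(degIds, c(downGenes, upGenes))
  tfEdges <- rbind(
    draw_edges(tfIds[tfModule == "down"], downGenes, 0.9),
    draw_edges(tfIds[tfModule == "up"], upGenes, 0.9),
    draw_edges(tfIds[tfModule != "background"], otherDegs, 0.03),
    draw_edges(tfIds[tfModule == "background"], degIds, 0.08)
  )
  if (is.null(tfEdges))
    tfEdges <- data.frame(tf = character(), target = character(),
                          stringsAsFactors = FALSE)
  tfEdges <- unique(tfEdges[order(tfEdges$tf, tfEdges$target), , drop = FALSE])
  rownames(tfEdges) <- NULL
  geneModules <- c(stats::setNames(rep("down", length(downGenes)), downGenes),
                   stats::setNames(rep("up", length(upGenes)), upGenes))

  ## --- PPI graph with a designated hub --------------------------------------
  hub <- "Akt1"
  ppiNodes <- sort(unique(c(protIds[depIdx], protIds[parents[plantIdx]])))
  ppiEdges <- data.frame(a = character(), b = character(),
                         stringsAsFactors = FALSE)
  if (length(ppiNodes) >= 4L) {
    nbg <- round(1.5 * length(ppiNodes))
    bg <- data.frame(
      a = sample(ppiNodes, nbg, replace = TRUE),
      b = sample(ppiNodes, nbg, replace = TRUE),
      stringsAsFactors = FALSE)
    bg <- bg[bg$a != bg$b, , drop = FALSE]
    sw <- bg$a > bg$b
    tmp <- bg$a[sw]; bg$a[sw] <- bg$b[sw]; bg$b[sw] <- tmp
    bg <- unique(bg)
    degBg <- table(factor(c(bg$a, bg$b), levels = ppiNodes))
    target <- min(length(ppiNodes), max(degBg) + 3L)
    hubTo <- sample(ppiNodes, target)
    ppiEdges <- unique(rbind(data.frame(a = hub, b = hubTo,
                                        stringsAsFactors = FALSE), bg))
    rownames(ppiEdges) <- NULL
  }

  ## --- gene sets -------------------------------------------------------------
  geneSets <- list()
  if (length(downGenes)) geneSets$cytoskeleton_transport <- downGenes
  if (length(upGenes)) geneSets$lipid_metabolism_signaling <- upGenes
  for (i in 1:3)
    geneSets[[sprintf("random_set_%d", i)]] <-
      sort(sample(geneIds, min(30L, nT)))
  attr(geneSets, "source_db") <- rep("synthetic", length(geneSets))

  ## --- bundle ----------------------------------------------------------------
  mapping <- data.frame(protein_id = protIds[seq_len(min(nP, nT))],
                        gene_id = geneIds[seq_len(min(nP, nT))],
                        stringsAsFactors = FALSE)
  truth <- new("GroundTruth",
    depIds = protIds[depIdx],
    depDirections = stats::setNames(depDir, protIds[depIdx]),
    degIds = geneIds[degIdx],
    degDirections = stats::setNames(degDir, geneIds[degIdx]),
    dphosphoIds = pepIds[plantIdx],
    dphosphoDirections = stats::setNames(plantDir, pepIds[plantIdx]),
    gofGeneIds = geneIds[gofIdx],
    lofGeneIds = geneIds[lofIdx],
    concordantPairs = data.frame(protein_id = protIds[concIdx],
                                 gene_id = geneIds[concIdx],
                                 stringsAsFactors = FALSE),
    tfModules = tfModule,
    geneModules = geneModules,
    hubNode = hub)

  list(design = design,
       proteins = abundanceTable(protMat, "protein"),
       phospho = abundanceTable(phosMat, "phosphopeptide"),
       transcripts = abundanceTable(tranMat, "transcript"),
       phosphoRecords = data.frame(peptide_id = pepIds,
                                   parent_protein_id = protIds[parents],
                                   site_descriptor = sites,
                                   ptmrs_score = ptmrs,
                                   stringsAsFactors = FALSE),
       mapping = mapping,
       tfEdges = tfEdges,
       ppiEdges = ppiEdges,
       geneSets = geneSets,
       truth = truth,
       config = config)
}

#' Write a simulated dataset bundle to a directory
#'
#' One plain-text file per table, re-readable with the package readers, plus
#' a JSON ground-truth ledger.
#'
#' @param bundle a bundle from [simulateDataset].
#' @param dir output directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return `dir`, invisibly.
#' @export
writeDataset <- function(bundle, dir, overwrite = FALSE) {
  if (dir.exists(dir) && length(dir(dir, all.files = TRUE, no.. = TRUE)) &&
      !overwrite)
    stop("directory ", dir, " exists and is not empty; ",
         "use overwrite = TRUE to replace its contents")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeSampleDesign(bundle$design, file.path(dir, "design.tsv"))
  writeAbundanceTable(bundle$proteins, file.path(dir, "proteins.tsv"))
  writeAbundanceTable(bundle$phospho, file.path(dir, "phosphopeptides.tsv"))
  writeAbundanceTable(bundle$transcripts, file.path(dir, "transcripts.tsv"))
  .write_tsv(bundle$phosphoRecords, file.path(dir, "phospho_records.tsv"))
  .write_tsv(bundle$mapping, file.path(dir, "mapping.tsv"))
  .write_tsv(bundle$tfEdges, file.path(dir, "tf_edges.tsv"))
  .write_tsv(bundle$ppiEdges, file.path(dir, "ppi_edges.tsv"))
  writeGmt(bundle$geneSets, file.path(dir, "gene_sets.gmt"))
  tr <- bundle$truth
  jsonlite::write_json(list(
    dep_ids = tr@depIds, dep_directions = tr@depDirections,
    deg_ids = tr@degIds, deg_directions = tr@degDirections,
    dphospho_ids = tr@dphosphoIds,
    dphospho_directions = tr@dphosphoDirections,
    gof_gene_ids = tr@gofGeneIds, lof_gene_ids = tr@lofGeneIds,
    concordant_pairs = tr@concordantPairs,
    tf_modules = as.list(tr@tfModules),
    gene_modules = as.list(tr@geneModules),
    hub_node = tr@hubNode,
    seed = bundle$config@seed
  ), file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a dataset bundle written by [writeDataset]
#'
#' @param dir directory written by [writeDataset].
#' @param reference reference condition passed to [readSampleDesign].
#' @return a bundle list (without `truth`/`config`, which are simulation
#'   metadata; the truth ledger is available in `ground_truth.json`).
#' @export
readDataset <- function(dir, reference = NULL) {
  list(
    design = readSampleDesign(file.path(dir, "design.tsv"), reference),
    proteins = readAbundanceTable(file.path(dir, "proteins.tsv"), "protein"),
    phospho = readAbundanceTable(file.path(dir, "phosphopeptides.tsv"),
                                 "phosphopeptide"),
    transcripts = readAbundanceTable(file.path(dir, "transcripts.tsv"),
                                     "transcript"),
    phosphoRecords = readPhosphoRecords(file.path(dir, "phospho_records.tsv")),
    mapping = readMapping(file.path(dir, "mapping.tsv")),
    tfEdges = readEdgeList(file.path(dir, "tf_edges.tsv")),
    ppiEdges = readEdgeList(file.path(dir, "ppi_edges.tsv")),
    geneSets = readGmt(file.path(dir, "gene_sets.gmt"))
  )
}
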