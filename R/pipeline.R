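# End-to-end orchestration: simulate (or load) a dataset, then run every
# analysis stage in dependency order, writing per-stage artifacts and a run
# manifest.

.PIPELINE_FIELDS <- c(
  "seed", "input_dir",
  "n_proteins", "n_transcripts", "n_phospho", "replicates",
  "wt_protein_replicates", "frac_dep", "frac_deg", "frac_dphospho",
  "effect_log2", "cv_noise", "frac_concordant", "n_gof", "n_lof", "n_tfs",
  "missing_rate",
  "alpha_adj", "log2fc_min", "z_dphospho", "z_concordance", "ptmrs_min",
  "pseudocount_ratio",
  "near_zero_band", "k_gene_clusters", "jaccard_collapse", "min_score"
)

#' Read a pipeline configuration
#'
#' A flat key:value file (YAML syntax) addressing every threshold and
#' simulation field; unknown keys are rejected before any computation. The
#' published settings are the defaults, so an empty config plus a seed is
#' the "paper-defaults" profile.
#'
#' @param path config file path.
#' @return named list of configuration values.
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  .validate_pipeline_config(cfg)
  cfg
}

.validate_pipeline_config <- function(cfg) {
  unknown <- setdiff(names(cfg), .PIPELINE_FIELDS)
  if (length(unknown))
    stop("config schema violation: unknown field(s): ",
         paste(unknown, collapse = ", "))
  if (is.null(cfg$input_dir) && is.null(cfg$seed))
    stop("config schema violation: need either 'seed' (simulate) or ",
         "'input_dir' (load)")
  if (!is.null(cfg$input_dir)) {
    needed <- file.path(cfg$input_dir,
                        c("design.tsv", "proteins.tsv", "phosphopeptides.tsv",
                          "transcripts.tsv", "phospho_records.tsv",
                          "mapping.tsv", "tf_edges.tsv", "ppi_edges.tsv",
                          "gene_sets.gmt"))
    miss <- needed[!file.exists(needed)]
    if (length(miss))
      stop("pre-flight: missing input file(s): ",
           paste(miss, collapse = ", "))
  }
  invisible(cfg)
}

.cfg_get <- function(cfg, key, default) {
  if (is.null(cfg[[key]])) default else cfg[[key]]
}

.cfg_thresholds <- function(cfg) {
  thresholds(
    alphaAdj = .cfg_get(cfg, "alpha_adj", 0.05),
    log2fcMin = .cfg_get(cfg, "log2fc_min", 0.585),
    zDphospho = .cfg_get(cfg, "z_dphospho", 1),
    zConcordance = .cfg_get(cfg, "z_concordance", 3.5),
    ptmrsMin = .cfg_get(cfg, "ptmrs_min", 50),
    pseudocountRatio = .cfg_get(cfg, "pseudocount_ratio", 1))
}

.cfg_simconfig <- function(cfg) {
  simulationConfig(
    seed = cfg$seed,
    nProteins = .cfg_get(cfg, "n_proteins", 2000L),
    nTranscripts = .cfg_get(cfg, "n_transcripts", 5000L),
    nPhospho = .cfg_get(cfg, "n_phospho", 60L),
    replicates = .cfg_get(cfg, "replicates", 3L),
    wtProteinReplicates = .cfg_get(cfg, "wt_protein_replicates", 4L),
    fracDep = .cfg_get(cfg, "frac_dep", 0.1),
    fracDeg = .cfg_get(cfg, "frac_deg", 0.1),
    fracDphospho = .cfg_get(cfg, "frac_dphospho", 0.25),
    effectLog2 = .cfg_get(cfg, "effect_log2", 2.0),
    cvNoise = .cfg_get(cfg, "cv_noise", 0.2),
    fracConcordant = .cfg_get(cfg, "frac_concordant", 0.2),
    nGof = .cfg_get(cfg, "n_gof", 40L),
    nLof = .cfg_get(cfg, "n_lof", 40L),
    nTfs = .cfg_get(cfg, "n_tfs", 29L),
    missingRate = .cfg_get(cfg, "missing_rate", 0))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Stages, in dependency order: dataset (simulate or load), ptmRS filter,
#' differential expression (pooled mutants versus reference for proteins;
#' per-mutant, pooled and control contrasts for transcripts), differential
#' phosphorylation (both strategies plus consensus), proteome-transcriptome
#' concordance, metagene classification, overrepresentation analysis,
#' TF-target matrix clustering, and the PPI network. Any stage failure halts
#' the run with a stage-named error. A JSON manifest records the config
#' snapshot, seed, per-stage row counts, file digests and package version;
#' re-running with an identical config reproduces identical outputs (the
#' manifest timestamp aside).
#'
#' @param config a config list or a path to a YAML key:value file (see
#'   [readPipelineConfig]).
#' @param out_dir output directory for stage artifacts and the manifest.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return (invisibly) a list with the main in-memory results and
#'   \code{manifest}.
#' @export
runPipeline <- function(config, out_dir, overwrite = FALSE) {
  cfg <- if (is.character(config)) readPipelineConfig(config)
         else .validate_pipeline_config(config)
  if (dir.exists(out_dir) &&
      length(dir(out_dir, all.files = TRUE, no.. = TRUE)) && !overwrite)
    stop("output directory ", out_dir, " exists and is not empty")
  th <- .cfg_thresholds(cfg)
  counts <- list()

  bundle <- .stage("dataset", {
    if (!is.null(cfg$input_dir)) readDataset(cfg$input_dir)
    else simulateDataset(.cfg_simconfig(cfg))
  })
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  design <- bundle$design
  ctrl <- conditions(design)[1L]
  ref <- referenceCondition(design)
  mutants <- setdiff(conditions(design), c(ctrl, ref))

  records <- .stage("ptmrs-filter",
                    filterPtmrs(bundle$phosphoRecords, th))
  counts$peptides_after_ptmrs <- nrow(records)

  ## differential expression -------------------------------------------------
  de <- .stage("de-filter", {
    protAllmut <- standinTest(bundle$proteins, design, test = mutants,
                              reference = ref, th = th)
    tranPerMut <- lapply(mutants, function(m)
      standinTest(bundle$transcripts, design, test = m, reference = ref,
                  th = th))
    names(tranPerMut) <- mutants
    tranAllmut <- standinTest(bundle$transcripts, design, test = mutants,
                              reference = ref, th = th)
    tranCtrl <- standinTest(bundle$transcripts, design, test = ctrl,
                            reference = ref, th = th)
    list(protAllmut = protAllmut, tranPerMut = tranPerMut,
         tranAllmut = tranAllmut, tranCtrl = tranCtrl)
  })
  writeContrastResult(de$protAllmut,
                      file.path(out_dir, "proteins_allmut_vs_ref.tsv"))
  writeContrastResult(de$tranAllmut,
                      file.path(out_dir, "transcripts_allmut_vs_ref.tsv"))
  writeContrastResult(de$tranCtrl,
                      file.path(out_dir, "transcripts_control_vs_ref.tsv"))
  for (m in mutants)
    writeContrastResult(de$tranPerMut[[m]],
                        file.path(out_dir, sprintf("transcripts_%s_vs_ref.tsv", m)))
  depReport <- applyThresholds(de$protAllmut, th)
  degSets <- lapply(de$tranPerMut, function(d) applyThresholds(d, th)$pass_fc)
  commonDegs <- .stage("deg-intersection", intersectDegs(degSets)$common)
  counts$deps_allmut <- depReport$n_pass_fc
  counts$degs_common <- length(commonDegs)

  ## differential phosphorylation --------------------------------------------
  dphos <- .stage("dphospho", {
    norm <- normalizePhospho(bundle$phospho, bundle$proteins, records)
    s1 <- dphosphoStrategy1(bundle$phospho, bundle$proteins, records,
                            design, mutants, th)
    s2 <- dphosphoStrategy2(bundle$phospho, bundle$proteins, records,
                            design, mutants, th)
    cons <- dphosphoConsensus(s1, s2)
    list(norm = norm, s1 = s1, s2 = s2, consensus = cons)
  })
  .write_tsv(do.call(rbind, dphos$s1), file.path(out_dir, "dphospho_strategy1.tsv"))
  .write_tsv(dphos$s2, file.path(out_dir, "dphospho_strategy2.tsv"))
  .write_tsv(data.frame(peptide_id = dphos$s2$peptide_id,
                        condition = dphos$s2$condition,
                        effect = dphos$s2$effect,
                        neg_log10_p_adj = -log10(pmax(dphos$s2$p_adj,
                                                      .Machine$double.xmin))),
             file.path(out_dir, "dphospho_volcano.tsv"))
  if (nrow(dphos$consensus))
    .write_tsv(dphos$consensus, file.path(out_dir, "dphospho_consensus.tsv"))
  counts$dphospho_consensus <- nrow(dphos$consensus)
  counts$dphospho_high_confidence <-
    sum(dphos$consensus$confidence == "high")

  ## concordance ---------------------------------------------------------------
  conc <- .stage("concordance", {
    deps <- de$protAllmut[de$protAllmut$feature_id %in% depReport$pass_fc, ,
                          drop = FALSE]
    pairs <- matchFeatures(deps, de$tranAllmut, bundle$mapping)
    removeOutliersAndCorrelate(pairs, th)
  })
  .write_tsv(conc$pairs, file.path(out_dir, "concordance_pairs.tsv"))
  jsonlite::write_json(conc[c("r", "n_kept", "n_removed",
                              "n_same_direction")],
                       file.path(out_dir, "concordance_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  counts$concordance_pairs_kept <- conc$n_kept

  ## metagene -------------------------------------------------------------------
  meta <- .stage("metagene",
                 metageneClassify(commonDegs, de$tranPerMut, de$tranCtrl,
                                  near_zero_band = .cfg_get(cfg,
                                    "near_zero_band", th@log2fcMin)))
  .write_tsv(meta$results, file.path(out_dir, "metagene_classes.tsv"))
  .write_tsv(meta$tests, file.path(out_dir, "metagene_tests.tsv"))
  .write_tsv(meta$long, file.path(out_dir, "metagene_long.tsv"))
  counts$metagene_lof <- sum(meta$results$class == "LoF")
  counts$metagene_gof <- sum(meta$results$class == "GoF")

  ## ORA -------------------------------------------------------------------------
  enr <- .stage("ora", {
    universe <- featureIds(bundle$transcripts)
    lapply(list(common = commonDegs,
                up = meta$results$gene_id[
                  meta$results$mean_log2fc_mut_vs_ref > 0],
                down = meta$results$gene_id[
                  meta$results$mean_log2fc_mut_vs_ref < 0]),
           function(q) if (length(q)) ora(q, bundle$geneSets, universe)
                       else NULL)
  })
  for (nm in names(enr))
    if (!is.null(enr[[nm]]) && nrow(enr[[nm]]))
      .write_tsv(enr[[nm]][, setdiff(names(enr[[nm]]), "overlap_genes")],
                 file.path(out_dir, sprintf("ora_%s.tsv", nm)))
  bubble <- selectBubbleTerms(enr$common,
                              jaccard_collapse = .cfg_get(cfg,
                                "jaccard_collapse", 0.75))
  if (!is.null(bubble) && nrow(bubble))
    .write_tsv(bubble[, c("set_name", "source_db", "k", "K", "p_adj")],
               file.path(out_dir, "ora_bubble.tsv"))

  ## TF-target clustering ---------------------------------------------------------
  tfc <- .stage("tf-cluster", {
    expressed <- union(featureIds(bundle$proteins),
                       featureIds(bundle$transcripts))
    mtx <- buildTfMatrix(commonDegs, bundle$tfEdges, expressed)
    cl <- twoWayCluster(mtx, k = .cfg_get(cfg, "k_gene_clusters", 2L))
    list(matrix = mtx, clusters = cl)
  })
  .write_tsv(data.frame(gene_id = rownames(tfc$matrix),
                        as.data.frame(tfc$matrix), check.names = FALSE),
             file.path(out_dir, "tf_matrix.tsv"))
  .write_tsv(data.frame(gene_id = names(tfc$clusters$gene_clusters),
                        cluster = as.integer(tfc$clusters$gene_clusters)),
             file.path(out_dir, "tf_gene_clusters.tsv"))
  counts$tf_matrix_genes <- nrow(tfc$matrix)
  counts$tf_matrix_tfs <- ncol(tfc$matrix)

  ## network -------------------------------------------------------------------------
  net <- .stage("network", {
    dphosParents <- unique(parentProteins(dphos$norm)[
      dphos$consensus$peptide_id])
    nodeSets <- list(DEP = depReport$pass_fc,
                     DPhospho = dphosParents[!is.na(dphosParents)],
                     TF = colnames(tfc$matrix))
    if (nrow(bundle$ppiEdges))
      nodeSets$seed <- unique(c(bundle$ppiEdges[[1L]],
                                bundle$ppiEdges[[2L]]))
    buildNetwork(bundle$ppiEdges, nodeSets,
                 min_score = .cfg_get(cfg, "min_score", NULL))
  })
  .write_tsv(net$nodes, file.path(out_dir, "network_nodes.tsv"))
  .write_tsv(net$edges, file.path(out_dir, "network_edges.tsv"))
  .write_tsv(rankHubs(net, 20L), file.path(out_dir, "network_hubs.tsv"))
  counts$network_nodes <- nrow(net$nodes)
  counts$network_edges <- nrow(net$edges)

  ## manifest -------------------------------------------------------------------------
  outputs <- sort(dir(out_dir, full.names = FALSE))
  digests <- as.list(tools::md5sum(file.path(out_dir, outputs)))
  names(digests) <- outputs
  manifest <- list(
    tool = "phosphoDiff",
    version = as.character(utils::packageVersion("phosphoDiff")),
    seed = cfg$seed,
    config = cfg,
    counts = counts,
    output_digests = digests,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(bundle = bundle, de = de, dep_report = depReport,
                 common_degs = commonDegs, dphospho = dphos,
                 concordance = conc, metagene = meta, ora = enr,
                 tf = tfc, network = net, manifest = manifest))
}
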