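#' @include AllClasses.R
NULL

#' Default pipeline configuration
#'
#' Nested list of every stage tunable with its default. Defaults follow the
#' documented module defaults (QC thresholds 500/1000/0.5, wilcox
#' min.pct 0.25 and logFC ln(1.5), CNV window 25, deviation ratio 3, lasso
#' alpha 1 at CV-min, random forest 1500 trees / mtry 10, 10 NMF factors,
#' ligand-receptor detection 0.2, PH cut-off 0.1).
#'
#' @param seed master seed for all stochastic stages.
#' @return a nested configuration list.
#' @export
pipelineConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    qc = list(minGenes = 500, minUmis = 1000, maxMito = 0.5,
              scaleFactor = 1e4),
    hvg = list(n = 2000),
    cluster = list(kNeighbors = 20, resolution = 1.0, nPcs = 50),
    cnv = list(winSize = 25, minCellsExpr = 10, devRatio = 3.0,
               maxNormalMix = 0.1, requireNormal = FALSE,
               resolution = 1.0),
    deg = list(minPct = 0.25, logfcThreshold = log(1.5)),
    signature = list(rMin = 0.5, degAlpha = 0.05, nTrees = 1500, mTry = 10,
                     importanceQuantile = 0.25, literalFloor = FALSE),
    programs = list(k = 10, topM = 50, minSamples = 2, cutHeight = 0.6,
                    maxIter = 500, minCells = 30),
    trajectory = list(nPcs = 30, rhoMin = 0.3, fdr = 0.05),
    communication = list(detect = 0.2),
    survival = list(phAlpha = 0.1, n = 300, hr = 2, censorRate = 0.2)
  )
}

.writeTsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes the study's analysis order on a conforming cohort: QC and
#' normalization, graph clustering, CNV profiling with malignant-cell
#' classification (on an epithelial subclustering, anchored on normal-mucosa
#' cells), cluster markers, the differentiation-signature cascade, tumor and
#' differentiation scores, per-sample NMF with cross-sample programs, the
#' trans-differentiation pseudotime, ligand-receptor edges, and median-split
#' survival analysis. Stage outputs are written to an append-only run
#' directory together with a deterministic \code{manifest.json} (no
#' timestamps), so identical inputs and seed give identical outputs. A
#' failing stage halts the run with an error naming the stage; outputs of
#' completed stages are preserved.
#'
#' @param input a SingleCellExperiment (with \code{lineage} and
#'   \code{pathology} in \code{colData}) or a directory readable by
#'   [readCohort()].
#' @param outDir output directory.
#' @param config a [pipelineConfig()] list.
#' @param survivalTab optional survival data.frame (id/time/event/
#'   expression); when NULL and \code{input} is a directory containing
#'   \code{survival.tsv} that file is used, otherwise a synthetic table is
#'   generated from the config.
#' @return the manifest list, invisibly.
#' @export
runPipeline <- function(input, outDir, config = pipelineConfig(),
                        survivalTab = NULL) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(input)) {
    if (is.null(survivalTab) &&
        file.exists(file.path(input, "survival.tsv")))
      survivalTab <- read.delim(file.path(input, "survival.tsv"))
    input <- readCohort(input)
  }
  sce <- input
  seed <- config$seed
  manifest <- list(package = "gastroscape",
                   version = as.character(utils::packageVersion("gastroscape")),
                   seed = seed, config = config, stages = list())
  state <- new.env()

  runStage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(res))
      jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, null = "null",
                           pretty = TRUE)
      stop("pipeline halted at stage '", name, "': ",
           conditionMessage(res), call. = FALSE)
    }
    manifest$stages[[name]] <<- c(list(status = "complete"), res)
  }

  runStage("qc", function() {
    sceF <- qcFilter(sce, config$qc$minGenes, config$qc$minUmis,
                     config$qc$maxMito)
    sceF <- logNormalize(sceF, config$qc$scaleFactor)
    state$sce <- sceF
    rep <- S4Vectors::metadata(sceF)$qc_report
    rep$thresholds <- as.list(rep$thresholds)
    rep
  })

  runStage("cluster", function() {
    sceF <- state$sce
    hvgs <- selectHvgs(sceF, min(config$hvg$n, nrow(sceF)))
    cl <- clusterCells(sceF, genes = hvgs,
                       kNeighbors = config$cluster$kNeighbors,
                       resolution = config$cluster$resolution,
                       nPcs = config$cluster$nPcs, seed = seed)
    sceF$cluster <- as.integer(as.character(cl))
    state$sce <- sceF
    state$hvgs <- hvgs
    .writeTsv(data.frame(cell_id = colnames(sceF), cluster = sceF$cluster),
              file.path(outDir, "clusters.tsv"))
    list(n_cells = ncol(sceF), n_clusters = length(unique(cl)))
  })

  runStage("cnv_malignancy", function() {
    sceF <- state$sce
    epi <- sceF[, sceF$lineage == "epithelial"]
    if (ncol(epi) < 50) stop("fewer than 50 epithelial cells")
    normalMask <- epi$pathology == "normal"
    if (!any(normalMask) && config$cnv$requireNormal)
      stop("no normal-mucosa cells present")
    subCl <- clusterCells(epi, genes = rownames(epi),
                          kNeighbors = min(20, ncol(epi) - 1),
                          resolution = config$cnv$resolution, seed = seed)
    prof <- smoothGenomic(epi, winSize = config$cnv$winSize,
                          minCellsExpr = config$cnv$minCellsExpr)
    prof <- cnvDeviation(prof, normalMask)
    calls <- classifyMalignant(prof, subCl, normalMask,
                               devRatio = config$cnv$devRatio,
                               maxNormalMix = config$cnv$maxNormalMix,
                               requireNormal = config$cnv$requireNormal)
    malig <- rep(NA, ncol(sceF))
    names(malig) <- colnames(sceF)
    malig[names(calls$malignant)] <- calls$malignant
    sceF$malignant <- malig
    state$sce <- sceF
    .writeTsv(data.frame(cell_id = names(deviationScores(prof)),
                         deviation = as.numeric(deviationScores(prof)),
                         cluster = as.character(subCl),
                         malignant = calls$malignant),
              file.path(outDir, "cnv_deviation.tsv"))
    .writeTsv(calls$calls, file.path(outDir, "malignancy_calls.tsv"))
    list(n_epithelial = ncol(epi), n_malignant = sum(calls$malignant),
         fallback = calls$fallback)
  })

  runStage("deg", function() {
    sceF <- state$sce
    deg <- wilcoxMarkers(sceF, sceF$cluster, minPct = config$deg$minPct,
                         logfcThreshold = config$deg$logfcThreshold)
    .writeTsv(deg, file.path(outDir, "cluster_markers.tsv"))
    list(n_markers = nrow(deg))
  })

  runStage("signature", function() {
    sceF <- state$sce
    sel <- !is.na(sceF$malignant) & sceF$malignant &
      sceF$pathology %in% c("DGC", "PDGC")
    sub <- sceF[, sel]
    sig <- deriveSignature(
      sub, sub$pathology,
      rMin = config$signature$rMin, degAlpha = config$signature$degAlpha,
      nTrees = config$signature$nTrees, mTry = config$signature$mTry,
      importanceQuantile = config$signature$importanceQuantile,
      literalFloor = config$signature$literalFloor, seed = seed)
    state$signature <- sig
    jsonlite::write_json(
      list(name = sig@name, genes = signatureGenes(sig),
           provenance = geneProvenance(sig), params = sig@params),
      file.path(outDir, "signature.json"),
      auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
    list(n_genes = length(signatureGenes(sig)),
         genes = signatureGenes(sig))
  })

  runStage("scores", function() {
    sceF <- state$sce
    epi <- sceF[, sceF$lineage == "epithelial" & !is.na(sceF$malignant)]
    ts <- tumorDiffScores(epi, epi$malignant, state$signature, seed = seed)
    .writeTsv(data.frame(cell_id = colnames(epi), tumor = ts$tumor,
                         diff = ts$diff, malignant = epi$malignant),
              file.path(outDir, "scores.tsv"))
    list(r_tumor_diff = ts$r, n_tumor_genes = length(ts$tumor_genes))
  })

  runStage("programs", function() {
    sceF <- state$sce
    malig <- !is.na(sceF$malignant) & sceF$malignant
    loads <- list()
    for (s in unique(sceF$sample_id[malig])) {
      cells <- malig & sceF$sample_id == s
      if (sum(cells) < max(config$programs$minCells, config$programs$k))
        next
      v <- nmfInput(sceF[, cells], state$hvgs)
      fit <- nmfFactorize(v, k = config$programs$k, seed = seed,
                          maxIter = config$programs$maxIter)
      loads[[s]] <- fit$loadings
    }
    if (length(loads) < 2) stop("fewer than 2 samples with enough malignant cells")
    ps <- clusterFactors(loads, topM = config$programs$topM,
                         minSamples = config$programs$minSamples,
                         cutHeight = config$programs$cutHeight)
    jsonlite::write_json(
      list(assignments = programAssignments(ps),
           program_genes = programGenes(ps)),
      file.path(outDir, "programs.json"),
      auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
    list(n_factors = nrow(programAssignments(ps)),
         n_programs = length(programGenes(ps)))
  })

  runStage("trajectory", function() {
    sceF <- state$sce
    epi <- sceF[, sceF$lineage == "epithelial" & !is.na(sceF$malignant)]
    anchors <- rep(NA_character_, ncol(epi))
    anchors[!epi$malignant] <- "non_malignant"
    anchors[epi$malignant & epi$pathology == "DGC"] <- "DGC"
    anchors[epi$malignant & epi$pathology == "NEC"] <- "NEC"
    hv <- intersect(state$hvgs, rownames(epi))
    path <- pseudotimePath(epi[hv, ], anchors,
                           nPcs = config$trajectory$nPcs, seed = seed)
    mono <- monotoneGenes(epi, path, rhoMin = config$trajectory$rhoMin,
                          fdr = config$trajectory$fdr)
    state$path <- path
    .writeTsv(data.frame(cell_id = names(pseudotimes(path)),
                         pseudotime = as.numeric(pseudotimes(path))),
              file.path(outDir, "pseudotime.tsv"))
    .writeTsv(mono$trends, file.path(outDir, "monotone_genes.tsv"))
    list(n_cells = ncol(epi),
         n_monotone = sum(mono$trends$significant))
  })

  runStage("communication", function() {
    sceF <- state$sce
    types <- sceF$lineage
    types[!is.na(sceF$malignant) & sceF$malignant] <- "malignant"
    pairs <- readLRPairs()
    edges <- extractEdges(sceF, types, pairs,
                          detect = config$communication$detect)
    .writeTsv(edges, file.path(outDir, "lr_edges.tsv"))
    list(n_edges = nrow(edges))
  })

  runStage("survival", function() {
    tab <- survivalTab
    if (is.null(tab))
      tab <- simulateSurvival(config$survival$n, config$survival$hr,
                              config$survival$censorRate, seed)
    km <- kmLogrank(tab)
    cx <- coxFit(tab, phAlpha = config$survival$phAlpha)
    jsonlite::write_json(
      list(logrank_chi2 = km$chi2, logrank_p = km$p,
           cox = cx[c("log_hazard", "se", "p", "ph_p", "ph_ok",
                      "converged")]),
      file.path(outDir, "survival.json"),
      auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
    list(n_subjects = nrow(tab), logrank_p = km$p,
         cox_log_hazard = cx$log_hazard)
  })

  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(manifest)
}
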