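suppressPackageStartupMessages({
  library(SingleCellExperiment)
  library(SummarizedExperiment)
})

# cached small cohorts so several test files can share one simulation
.cohortCache <- new.env(parent = emptyenv())

cachedCohort <- function(key, maker) {
  if (!exists(key, envir = .cohortCache))
    assign(key, maker(), envir = .cohortCache)
  get(key, envir = .cohortCache)
}

# small full-structure cohort (all 14 samples, scaled down)
smallCohortRaw <- function(seed = 1) {
  cachedCohort(paste0("raw", seed), function()
    simulateCohort(cohortConfig(nCellsPerSample = 150, nGenes = 1200),
                   seed = seed))
}

smallCohort <- function(seed = 1) {
  cachedCohort(paste0("small", seed), function()
    logNormalize(qcFilter(smallCohortRaw(seed))))
}

groundTruth <- function(sce) metadata(sce)$ground_truth

# tumor-only design used for the signature cascade
cascadeSamples <- function() {
  data.frame(sample_id = c(paste0("D", 1:6), paste0("P", 1:6)),
             pathology = rep(c("DGC", "PDGC"), each = 6),
             immune_class = rep(c("rich", "poor"), 6),
             stringsAsFactors = FALSE)
}

cascadeCohort <- function(seed, nCells = 300, nGenes = 900) {
  sce <- simulateCohort(cohortConfig(nCellsPerSample = nCells,
                                     nGenes = nGenes,
                                     samples = cascadeSamples()),
                        seed = seed)
  logNormalize(qcFilter(sce))
}

# CNV benchmark: one normal and one tumor sample, a broad copy-3 gain plus
# a copy-1 loss
cnvCloneCohort <- function(seed, nCells = 400) {
  samp <- data.frame(sample_id = c("N1", "T1"),
                     pathology = c("normal", "DGC"),
                     immune_class = c(NA, "poor"))
  segs <- data.frame(chrom = c("chr1", "chr2"), start = c(1e6, 5e6),
                     end = c(7e6, 8e6), copy = c(3L, 1L))
  sce <- simulateCohort(cohortConfig(nCellsPerSample = nCells, nGenes = 800,
                                     samples = samp, cnvSegments = segs),
                        seed = seed)
  logNormalize(qcFilter(sce))
}

# trajectory benchmark: the path poles plus one mid-path tumor
trajectoryCohort <- function(seed, nCells = 250) {
  samp <- data.frame(sample_id = c("N1", "D1", "D2", "E1"),
                     pathology = c("normal", "DGC", "DGC", "NEC"),
                     immune_class = c(NA, "poor", "poor", "poor"))
  sce <- simulateCohort(cohortConfig(nCellsPerSample = nCells,
                                     nGenes = 1000, samples = samp),
                        seed = seed)
  logNormalize(qcFilter(sce))
}

# program benchmark: four tumors sharing three strong expression programs
programCohort <- function(seed, nCells = 800) {
  samp <- data.frame(sample_id = paste0("T", 1:4),
                     pathology = rep(c("DGC", "PDGC"), 2),
                     immune_class = rep("poor", 4))
  sce <- simulateCohort(cohortConfig(nCellsPerSample = nCells, nGenes = 700,
                                     samples = samp, programFold = 10),
                        seed = seed)
  logNormalize(qcFilter(sce))
}

epithelialAnchors <- function(sce) {
  truth <- groundTruth(sce)
  epi <- sce[, sce$lineage == "epithelial"]
  m <- truth$malignant[colnames(epi)]
  anchors <- rep(NA_character_, ncol(epi))
  anchors[!m] <- "non_malignant"
  anchors[m & epi$pathology == "DGC"] <- "DGC"
  anchors[m & epi$pathology == "NEC"] <- "NEC"
  list(epi = epi, anchors = anchors, malignant = m)
}

# adjusted Rand index between two labelings
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# independent brute-force rank-sum oracle: full enumeration of group
# assignments (two-sided, symmetric permutation distribution)
enumRankSumP <- function(values, nA, cmb = NULL) {
  n <- length(values)
  if (is.null(cmb)) cmb <- utils::combn(n, nA)
  r <- rank(values)
  obs <- sum(r[seq_len(nA)])
  sums <- colSums(matrix(r[cmb], nrow = nA))
  mu <- nA * (n + 1) / 2
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}
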