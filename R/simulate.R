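#' @include AllClasses.R
NULL

# -- gene panels ---------------------------------------------------------

.lineages <- c("epithelial", "fibroblast", "endothelial", "myeloid",
               "tnk", "b", "plasma", "mast")

.lineageMarkers <- list(
  epithelial  = c("EPCAM", "KRT8"),
  fibroblast  = c("THY1", "DCN"),
  endothelial = c("PECAM1", "CDH5"),
  myeloid     = c("C1QA", "CD163"),
  tnk         = c("CD3D", "CD3E"),
  b           = c("CD79A", "MS4A1"),
  plasma      = "MZB1",
  mast        = c("KIT", "TPSAB1")
)

.diffGenes <- c("AGR3", "CLDN3", "CLDN4", "FABP1", "LGALS4", "PHGR1",
                "MYH14", "S100A14")

# the halo of the differentiation program: same latent driver, weaker fold;
# these populate the low-contribution tail that the lasso/random-forest
# trimming is meant to remove
.weakDiffGenes <- c("S100A10", "CDH17", "VILL", "ANXA13", "KRT19",
                    "EPS8L3", "MYO1A", "PRAP1", "FAM3B", "SPINK4")

.exclusionGenes <- c("TM4SF20", "HEPH", "LINC01133", "PPP1R1B", "AKR1C3",
                     "REEP6")

# down- and upregulated along the adenocarcinoma -> neuroendocrine path:
# mucosa/adenocarcinoma genes fade while neuroendocrine genes rise
.gradientDown <- c("KRT20", "PIGR", "MUC1", "CEACAM5", "CLDN18", "TFF1",
                   "TFF3", "GKN1", "GKN2", "LIPF", "REG1A")
.gradientUp <- c("PDCD5", "CPNE1", "PDCD2", "GLO1", "APOA1", "CGA",
                 "CHGA", "CHGB", "CTAG2", "SCG3", "SCG5", "PCSK1N",
                 "TAC1", "INSM1", "SYP")

.ifnGenes <- c("ISG15", "IFI6", "STAT1", "IRF1", "GBP1", "IFITM3", "B2M",
               "CD74", "CCL20", "CCL25", "HLA-DRA", "HLA-DPA1")

# shared malignancy program; the EMT-flavoured half is stronger in PDGC
.malignancyGenes <- c("VIM", "LAMB3", "LAMC2", "COL6A1", "COL17A1", "HIF1A",
                      "S100A2", "CAV1", "CAV2", "ANXA1", "SPARC", "FN1",
                      "COL1A1", "COL3A1", "ITGA3", "ITGB4", "PLAU", "TNC",
                      "SDC1", "KRT17")

# gene expressed in differentiated tumors but too lowly to survive the
# expression floor of the signature cascade
.floorTrapGene <- "PGC"

# ligand-receptor repertoire: exhaustion/costimulation-related ligands on
# malignant cells, their receptors on T/NK (and one on myeloid) cells
.lrLigands <- c("LGALS3", "CEACAM1", "NECTIN4", "HLA-B", "MYL9", "TNFSF10")
.lrReceptorsT <- c("LAG3", "HAVCR2", "TIGIT", "KLRD1", "CD69")
.lrReceptorsM <- "TNFRSF11B"

.defaultSamples <- function() {
  data.frame(
    sample_id = c("N1", paste0("D", 1:6), paste0("P", 1:6), "E1"),
    pathology = c("normal", rep("DGC", 6), rep("PDGC", 6), "NEC"),
    immune_class = c(NA, "rich", "poor", "rich", "poor", "rich", "poor",
                     "rich", "poor", "rich", "poor", "rich", "poor", "poor"),
    stringsAsFactors = FALSE
  )
}

.defaultCnvSegments <- function() {
  data.frame(
    chrom = c("chr1", "chr2"),
    start = c(1e6, 5e6),
    end   = c(7e6, 8e6),
    copy  = c(3L, 1L)
  )
}

# -- configuration -------------------------------------------------------

#' Configure the synthetic gastric-cancer cohort generator
#'
#' Builds the settings list consumed by [simulateCohort()]. The defaults
#' emulate the design of a pathology-informed gastric cancer cohort: 14
#' samples (1 normal mucosa, 6 differentiated (DGC), 6 poorly differentiated
#' (PDGC) adenocarcinomas and 1 neuroendocrine carcinoma (NEC)), eight major
#' cell lineages with canonical marker genes, aneuploid malignant epithelial
#' cells, an 8-gene differentiation program elevated in DGC, an
#' interferon-response panel elevated in immune-rich tumors, shared
#' transcriptomic programs among malignant cells, and a DGC -> intermediate
#' -> NEC expression gradient tied to a latent pseudotime.
#'
#' Counts are negative binomial with gene-level means drawn log-normally and
#' a shared dispersion; per-cell library sizes are log-normal. A configurable
#' fraction of cells is planted to fail quality control (half too shallow,
#' half with excessive mitochondrial load).
#'
#' @param nCellsPerSample cells drawn per sample.
#' @param nGenes total genes in the toy genome (2 chromosomes of 10 Mb plus a
#'   small mitochondrial contig).
#' @param samples data.frame with columns \code{sample_id}, \code{pathology}
#'   (normal/DGC/PDGC/NEC) and \code{immune_class} (rich/poor/NA).
#' @param dispersion shared negative-binomial dispersion (size = 1/dispersion).
#' @param librarySdLog sd(log) of the per-cell library-size factor.
#' @param markerFold fold elevation of lineage marker genes (must be >= 4 to
#'   make markers unambiguous; >= 1 enforced).
#' @param lineageProgramSize,lineageProgramFold size and fold of the broader
#'   lineage-specific expression programs.
#' @param malignantFrac fraction of tumor-sample epithelial cells that are
#'   malignant (NEC uses \code{necMalignantFrac}).
#' @param necMalignantFrac malignant fraction for the NEC sample.
#' @param cnvSegments data.frame(chrom, start, end, copy) of clone CNV
#'   segments shared by all malignant cells; copies in 0:4 multiply gene
#'   means by copy/2.
#' @param diffFold fold span of the planted differentiation program (applied
#'   as fold^d where d in [0,1] is the cell's differentiation level).
#' @param diffWeakFold fold span of the weaker halo of the differentiation
#'   program (the low-contribution candidates the cascade should trim).
#' @param exclusionFold fold span of the curated exclusion genes (planted on
#'   the same latent driver so they reach the late cascade stages and are
#'   removed by the exclusion list, as curation — not statistics — dictates).
#' @param gradientFold fold span of the monotone trans-differentiation genes.
#' @param malignancyFoldDGC,malignancyFoldPDGC fold of the shared malignancy
#'   program in DGC vs PDGC/NEC malignant cells.
#' @param ifnFold fold of the interferon-response panel in malignant cells of
#'   immune-rich tumors.
#' @param nPrograms,programSize,programFold planted intra-tumoral expression
#'   programs (each malignant cell is dominated by one of them).
#' @param lrLigandFold fold elevation of the exhaustion/costimulation
#'   ligand repertoire on malignant cells (their receptors are expressed by
#'   T/NK and myeloid cells).
#' @param tumorEffects master switch. \code{TRUE} plants the full tumor
#'   structure. \code{FALSE} keeps the same lineage panel, sample design and
#'   ground-truth labels but leaves tumor expression unperturbed, producing
#'   one well-separated population per major cell type — the configuration
#'   used to benchmark lineage-cluster recovery.
#' @param nMitoGenes,qcFailFrac mitochondrial contig size and the fraction of
#'   cells planted to fail QC.
#'
#' @return a list of class \code{gastroscape_config}.
#' @seealso [simulateCohort()]
#' @export
cohortConfig <- function(nCellsPerSample = 800,
                         nGenes = 2000,
                         samples = .defaultSamples(),
                         dispersion = 0.5,
                         librarySdLog = 0.3,
                         markerFold = 8,
                         lineageProgramSize = 50,
                         lineageProgramFold = 6,
                         malignantFrac = 0.75,
                         necMalignantFrac = 0.9,
                         cnvSegments = .defaultCnvSegments(),
                         diffFold = 8,
                         diffWeakFold = 1.5,
                         exclusionFold = 4,
                         gradientFold = 32,
                         malignancyFoldDGC = 3,
                         malignancyFoldPDGC = 6,
                         ifnFold = 4,
                         nPrograms = 3,
                         programSize = 30,
                         programFold = 4,
                         lrLigandFold = 3,
                         tumorEffects = TRUE,
                         nMitoGenes = 20,
                         qcFailFrac = 0.05) {
  if (nCellsPerSample <= 0 || nGenes <= 0 || nrow(samples) == 0)
    stop("non-positive dimensions")
  folds <- c(markerFold, lineageProgramFold, diffFold, diffWeakFold,
             exclusionFold, gradientFold, malignancyFoldDGC,
             malignancyFoldPDGC, ifnFold, programFold, lrLigandFold)
  if (any(folds < 1)) stop("effect sizes below 1 are rejected")
  if (!all(c("sample_id", "pathology", "immune_class") %in% colnames(samples)))
    stop("samples must have sample_id/pathology/immune_class columns")
  if (!all(samples$pathology %in% c("normal", "DGC", "PDGC", "NEC")))
    stop("pathology must be one of normal/DGC/PDGC/NEC")
  if (!is.null(cnvSegments)) {
    if (!all(cnvSegments$copy %in% 0:4))
      stop("copy numbers must lie in 0:4")
  }
  cfg <- as.list(environment())
  class(cfg) <- "gastroscape_config"
  cfg
}

# derive a per-sample RNG seed from the master seed (kept < 2^31)
.sampleSeed <- function(seed, i) {
  as.integer(((as.numeric(seed) %% 1000003) * 1009 + i * 7919) %% 2147483647)
}

.genePanel <- function(cfg) {
  markers <- unlist(.lineageMarkers, use.names = FALSE)
  progGenes <- lapply(.lineages, function(l)
    sprintf("%s.P%02d", toupper(substr(l, 1, 3)), seq_len(cfg$lineageProgramSize)))
  names(progGenes) <- .lineages
  mpGenes <- lapply(seq_len(cfg$nPrograms), function(p)
    sprintf("MP%d.G%02d", p, seq_len(cfg$programSize)))
  names(mpGenes) <- paste0("MP", seq_len(cfg$nPrograms))
  mito <- sprintf("MTG%02d", seq_len(cfg$nMitoGenes))
  special <- c(markers, unlist(progGenes), .diffGenes, .weakDiffGenes,
               .exclusionGenes,
               .floorTrapGene, .gradientDown, .gradientUp, .ifnGenes,
               .malignancyGenes, .lrLigands, .lrReceptorsT, .lrReceptorsM,
               unlist(mpGenes), mito)
  stopifnot(!anyDuplicated(special))
  nFill <- cfg$nGenes - length(special)
  if (nFill < 0)
    stop("nGenes too small for the configured gene panels (need >= ",
         length(special), ")")
  filler <- sprintf("G%04d", seq_len(nFill))
  list(genes = c(special, filler), markers = markers,
       lineageProgram = progGenes, metaPrograms = mpGenes, mito = mito)
}

# -- cohort generator ----------------------------------------------------

#' Simulate a synthetic gastric-cancer scRNA-seq cohort with ground truth
#'
#' Draws a multi-sample UMI count matrix with the statistical structure the
#' downstream analysis assumes (see [cohortConfig()]) and returns it as a
#' \linkS4class{SingleCellExperiment}: \code{counts} assay (genes x cells,
#' sparse), per-cell metadata in \code{colData} (sample, pathology,
#' immune class, lineage), the toy genome annotation in \code{rowData}
#' (chromosome, 0-based half-open coordinates, mitochondrial flag), and the
#' full ground truth in \code{metadata(sce)$ground_truth} (lineage and
#' malignancy per cell, CNV segments, planted differentiation/program genes,
#' latent pseudotime for epithelial cells, planted QC failures).
#'
#' One RNG stream per sample is derived from the master seed, so a sample's
#' cells are reproducible independently of the others.
#'
#' @param config a [cohortConfig()] list.
#' @param seed integer master seed.
#' @return a \linkS4class{SingleCellExperiment}.
#' @examples
#' sce <- simulateCohort(cohortConfig(nCellsPerSample = 60, nGenes = 800),
#'                       seed = 1)
#' table(sce$pathology)
#' @export
simulateCohort <- function(config = cohortConfig(), seed = 1L) {
  stopifnot(inherits(config, "gastroscape_config"))
  cfg <- config
  panel <- .genePanel(cfg)
  genes <- panel$genes
  G <- length(genes)

  # gene-level parameters from the master stream
  set.seed(as.integer(seed %% 2147483647))
  baseMu <- rlnorm(G, meanlog = -0.7, sdlog = 1.2)
  names(baseMu) <- genes
  structural <- c(panel$markers, unlist(panel$lineageProgram))
  baseMu[structural] <- rlnorm(length(structural), meanlog = 0.2, sdlog = 0.3)
  themed <- c(.weakDiffGenes, .exclusionGenes, .gradientDown, .gradientUp,
              .ifnGenes, .malignancyGenes, .lrLigands, .lrReceptorsT,
              .lrReceptorsM, unlist(panel$metaPrograms))
  baseMu[themed] <- rlnorm(length(themed), meanlog = 0.1, sdlog = 0.3)
  # the core differentiation program sits at a solid, even baseline so its
  # per-gene signal is homogeneous; the curated exclusion genes are highly
  # expressed but carry a weaker fold
  baseMu[.diffGenes] <- rlnorm(length(.diffGenes), meanlog = 0.3,
                               sdlog = 0.05)
  baseMu[.exclusionGenes] <- rlnorm(length(.exclusionGenes), meanlog = 0.6,
                                    sdlog = 0.15)
  baseMu[panel$mito] <- rlnorm(length(panel$mito), meanlog = log(10),
                               sdlog = 0.2)
  baseMu[.floorTrapGene] <- 0.06

  ann <- .annotateGenome(genes, panel$mito)
  cnvMult <- rep(1, G)
  names(cnvMult) <- genes
  if (cfg$tumorEffects && !is.null(cfg$cnvSegments)) {
    for (i in seq_len(nrow(cfg$cnvSegments))) {
      seg <- cfg$cnvSegments[i, ]
      hit <- ann$chrom == seg$chrom & ann$start < seg$end & ann$end > seg$start
      cnvMult[hit] <- seg$copy / 2
    }
  }

  lineProps <- list(
    normal = c(epithelial = 0.30, fibroblast = 0.12, endothelial = 0.06,
               myeloid = 0.12, tnk = 0.20, b = 0.10, plasma = 0.06,
               mast = 0.04),
    tumor  = c(epithelial = 0.35, fibroblast = 0.08, endothelial = 0.06,
               myeloid = 0.12, tnk = 0.20, b = 0.08, plasma = 0.05,
               mast = 0.06)
  )

  sampleOut <- vector("list", nrow(cfg$samples))
  for (s in seq_len(nrow(cfg$samples))) {
    set.seed(.sampleSeed(seed, s))
    sampleOut[[s]] <- .simulateSample(cfg, panel, baseMu, cnvMult,
                                      cfg$samples[s, ], lineProps)
  }

  counts <- do.call(cbind, lapply(sampleOut, `[[`, "counts"))
  meta <- do.call(rbind, lapply(sampleOut, `[[`, "meta"))
  rownames(meta) <- meta$cell_id
  colnames(counts) <- meta$cell_id
  rownames(counts) <- genes

  truth <- list(
    lineage = setNames(meta$lineage, meta$cell_id),
    malignant = setNames(meta$malignant_true, meta$cell_id),
    cnv_segments = if (cfg$tumorEffects) cfg$cnvSegments else
      cfg$cnvSegments[0, ],
    differentiation_genes = .diffGenes,
    weak_differentiation_genes = .weakDiffGenes,
    exclusion_genes = .exclusionGenes,
    floor_trap_gene = .floorTrapGene,
    gradient_down = c(.gradientDown, .diffGenes),
    gradient_up = .gradientUp,
    ifn_genes = .ifnGenes,
    malignancy_genes = .malignancyGenes,
    program_genes = panel$metaPrograms,
    program_of = setNames(meta$program_true, meta$cell_id),
    pseudotime_true = setNames(meta$pseudotime_true, meta$cell_id)[
      meta$lineage == "epithelial"],
    qc_fail_cells = meta$cell_id[meta$qc_fail != "none"],
    survival_effect = NA_real_
  )

  cd <- meta[, c("cell_id", "sample_id", "pathology", "immune_class",
                 "lineage")]
  cd$cluster <- NA_integer_
  cd$malignant <- NA  # to be filled by classification, not ground truth

  rd <- ann
  # start/end are reserved rowData names in the container
  names(rd)[names(rd) == "start"] <- "start_bp"
  names(rd)[names(rd) == "end"] <- "end_bp"
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(rd, row.names = genes),
    colData = S4Vectors::DataFrame(cd, row.names = meta$cell_id),
    metadata = list(ground_truth = truth, config = cfg)
  )
  sce
}

.annotateGenome <- function(genes, mito) {
  G <- length(genes)
  isMito <- genes %in% mito
  n <- sum(!isMito)
  chrom <- rep(NA_character_, G)
  start <- integer(G)
  # nuclear genes alternate deterministically across the two 10 Mb
  # chromosomes; positions spread evenly with a seeded jitter drawn from the
  # active stream
  nuclear <- which(!isMito)
  half <- ceiling(n / 2)
  chrom[nuclear[seq_len(half)]] <- "chr1"
  chrom[nuclear[seq(half + 1, n)]] <- "chr2"
  for (ch in c("chr1", "chr2")) {
    idx <- which(chrom == ch)
    pos <- sort(sample.int(1e7 - 2000, length(idx)))
    start[idx] <- pos
  }
  chrom[isMito] <- "MT"
  start[isMito] <- seq(0, by = 800, length.out = sum(isMito))
  data.frame(
    gene_id = genes, chrom = chrom, start = start, end = start + 1000L,
    is_mitochondrial = isMito, stringsAsFactors = FALSE
  )
}

.simulateSample <- function(cfg, panel, baseMu, cnvMult, sampleRow,
                            lineProps) {
  n <- cfg$nCellsPerSample
  G <- length(baseMu)
  genes <- names(baseMu)
  pathology <- sampleRow$pathology
  props <- if (pathology == "normal") lineProps$normal else lineProps$tumor
  nLin <- drop(rmultinom(1, n, props))
  lineage <- rep(names(nLin), nLin)

  malig <- rep(FALSE, n)
  epi <- lineage == "epithelial"
  if (pathology != "normal") {
    frac <- if (pathology == "NEC") cfg$necMalignantFrac else cfg$malignantFrac
    malig[epi] <- runif(sum(epi)) < frac
  }

  # latent pseudotime t (position on the non-malignant -> DGC -> NEC path)
  # and differentiation level d for every epithelial cell
  t <- rep(NA_real_, n)
  d <- rep(NA_real_, n)
  nonmal <- epi & !malig
  t[nonmal] <- runif(sum(nonmal), 0, 0.25)
  d[nonmal] <- 1 - t[nonmal]
  if (pathology == "DGC") {
    # differentiation level varies between DGC cells independently of the
    # cell's path position
    t[malig] <- runif(sum(malig), 0.25, 0.5)
    d[malig] <- runif(sum(malig), 0.5, 0.75)
  } else if (pathology == "PDGC") {
    # PDGC sits off the DGC->NEC path: mid-range path position, but a
    # differentiation level well below DGC
    t[malig] <- runif(sum(malig), 0.3, 0.6)
    d[malig] <- runif(sum(malig), 0.1, 0.3)
  } else if (pathology == "NEC") {
    t[malig] <- runif(sum(malig), 0.5, 1)
    d[malig] <- 1 - t[malig]
  }

  mu <- matrix(baseMu, nrow = G, ncol = n, dimnames = list(genes, NULL))
  # receptor expression is part of the immune lineages' biology
  mu[.lrReceptorsT, lineage == "tnk"] <-
    mu[.lrReceptorsT, lineage == "tnk"] * 4
  mu[.lrReceptorsM, lineage == "myeloid"] <-
    mu[.lrReceptorsM, lineage == "myeloid"] * 4
  for (lin in .lineages) {
    cells <- lineage == lin
    if (!any(cells)) next
    mu[panel$lineageProgram[[lin]], cells] <-
      mu[panel$lineageProgram[[lin]], cells] * cfg$lineageProgramFold
    mu[.lineageMarkers[[lin]], cells] <-
      mu[.lineageMarkers[[lin]], cells] * cfg$markerFold
  }

  programOf <- rep(NA_integer_, n)
  if (cfg$tumorEffects) {
    if (any(malig)) {
      mu[, malig] <- mu[, malig] * cnvMult
      mFold <- if (pathology == "DGC") cfg$malignancyFoldDGC else
        cfg$malignancyFoldPDGC
      mu[.malignancyGenes, malig] <- mu[.malignancyGenes, malig] * mFold
      mu[.lrLigands, malig] <- mu[.lrLigands, malig] * cfg$lrLigandFold
      if (identical(sampleRow$immune_class, "rich"))
        mu[.ifnGenes, malig] <- mu[.ifnGenes, malig] * cfg$ifnFold
      programOf[malig] <- sample.int(cfg$nPrograms, sum(malig),
                                     replace = TRUE)
      for (p in seq_len(cfg$nPrograms)) {
        cells <- which(programOf == p)
        if (length(cells))
          mu[panel$metaPrograms[[p]], cells] <-
            mu[panel$metaPrograms[[p]], cells] * cfg$programFold
      }
    }
    # differentiation program (level d: high in normal/DGC, low in PDGC and
    # late path positions) and monotone path genes (driven by t alone)
    if (any(epi)) {
      dn <- c(.diffGenes, .floorTrapGene)
      mu[dn, epi] <- mu[dn, epi] *
        matrix(cfg$diffFold^d[epi], nrow = length(dn), ncol = sum(epi),
               byrow = TRUE)
      # curated exclusion genes ride the same driver at intermediate
      # strength; the weak halo is near the candidacy boundary
      mu[.exclusionGenes, epi] <- mu[.exclusionGenes, epi] *
        matrix(cfg$exclusionFold^d[epi], nrow = length(.exclusionGenes),
               ncol = sum(epi), byrow = TRUE)
      mu[.weakDiffGenes, epi] <- mu[.weakDiffGenes, epi] *
        matrix(cfg$diffWeakFold^d[epi], nrow = length(.weakDiffGenes),
               ncol = sum(epi), byrow = TRUE)
      mu[.gradientDown, epi] <- mu[.gradientDown, epi] *
        matrix(cfg$gradientFold^(1 - t[epi]), nrow = length(.gradientDown),
               ncol = sum(epi), byrow = TRUE)
      mu[.gradientUp, epi] <- mu[.gradientUp, epi] *
        matrix(cfg$gradientFold^t[epi], nrow = length(.gradientUp),
               ncol = sum(epi), byrow = TRUE)
    }
  }

  lib <- rlnorm(n, 0, cfg$librarySdLog)
  qcFail <- rep("none", n)
  nFail <- round(cfg$qcFailFrac * n)
  if (nFail > 0) {
    failIdx <- sample.int(n, nFail)
    shallow <- failIdx[seq_len(ceiling(nFail / 2))]
    mitoHi <- setdiff(failIdx, shallow)
    qcFail[shallow] <- "shallow"
    qcFail[mitoHi] <- "mito"
    lib[shallow] <- lib[shallow] * 0.06
    if (length(mitoHi))
      mu[panel$mito, mitoHi] <- mu[panel$mito, mitoHi] * 20
  }

  muCell <- mu * rep(lib, each = G)
  cnts <- rnbinom(G * n, mu = as.vector(muCell), size = 1 / cfg$dispersion)
  counts <- Matrix::Matrix(matrix(cnts, nrow = G), sparse = TRUE)

  meta <- data.frame(
    cell_id = sprintf("%s_C%04d", sampleRow$sample_id, seq_len(n)),
    sample_id = sampleRow$sample_id,
    pathology = pathology,
    immune_class = if (pathology == "normal") NA_character_ else
      sampleRow$immune_class,
    lineage = lineage,
    malignant_true = malig,
    pseudotime_true = t,
    program_true = programOf,
    qc_fail = qcFail,
    stringsAsFactors = FALSE
  )
  list(counts = counts, meta = meta)
}

# -- survival generator --------------------------------------------------

#' Simulate a median-split survival cohort
#'
#' Generates exponential event times in which the half of subjects with
#' above-median expression has its hazard multiplied by \code{hr}, with
#' independent exponential censoring calibrated so each subject is censored
#' with probability \code{censorRate}.
#'
#' @param n number of subjects (>= 20).
#' @param hr hazard ratio of the high-expression group (> 0).
#' @param censorRate probability of censoring, in [0, 1).
#' @param seed integer seed.
#' @return data.frame with columns \code{id}, \code{time}, \code{event},
#'   \code{expression}.
#' @export
simulateSurvival <- function(n, hr = 1, censorRate = 0, seed = 1L) {
  if (n < 20) stop("n must be at least 20")
  if (hr <= 0) stop("hr must be positive")
  if (censorRate < 0 || censorRate >= 1)
    stop("censorRate must lie in [0, 1)")
  set.seed(as.integer(seed %% 2147483647))
  expression <- rnorm(n)
  high <- expression > median(expression)
  lambda <- 0.01 * ifelse(high, hr, 1)
  tEvent <- rexp(n, lambda)
  if (censorRate > 0) {
    cens <- rexp(n, lambda * censorRate / (1 - censorRate))
    time <- pmin(tEvent, cens)
    event <- as.integer(tEvent <= cens)
  } else {
    time <- tEvent
    event <- rep(1L, n)
  }
  data.frame(id = sprintf("S%04d", seq_len(n)), time = time, event = event,
             expression = expression)
}
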