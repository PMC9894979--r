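#' @include AllClasses.R
NULL

#' Quality-control filtering of cells
#'
#' Retains cells with strictly more than \code{minGenes} detected genes,
#' strictly more than \code{minUmis} total transcripts and a mitochondrial
#' fraction strictly below \code{maxMito}. Mitochondrial genes are identified
#' by the \code{is_mitochondrial} flag of the gene annotation (not by a name
#' prefix). The removal counts per criterion are attached as
#' \code{metadata(sce)$qc_report}.
#'
#' @param sce a \linkS4class{SingleCellExperiment} with a \code{counts}
#'   assay and an \code{is_mitochondrial} column in \code{rowData}.
#' @param minGenes,minUmis,maxMito the three thresholds.
#' @return the filtered SingleCellExperiment.
#' @export
qcFilter <- function(sce, minGenes = 500, minUmis = 1000, maxMito = 0.5) {
  counts <- SummarizedExperiment::assay(sce, "counts")
  mito <- SummarizedExperiment::rowData(sce)$is_mitochondrial
  if (is.null(mito))
    stop("rowData(sce)$is_mitochondrial is required for QC filtering")
  nGenes <- Matrix::colSums(counts > 0)
  nUmis <- Matrix::colSums(counts)
  mitoFrac <- ifelse(nUmis > 0,
                     Matrix::colSums(counts[mito, , drop = FALSE]) / nUmis, 1)
  passGenes <- nGenes > minGenes
  passUmis <- nUmis > minUmis
  passMito <- mitoFrac < maxMito
  keep <- passGenes & passUmis & passMito
  if (!any(keep)) {
    cond <- simpleError("all cells failed QC")
    class(cond) <- c("allCellsFailedQC", class(cond))
    stop(cond)
  }
  report <- list(
    n_input = ncol(sce),
    n_kept = sum(keep),
    removed_low_genes = sum(!passGenes),
    removed_low_umis = sum(!passUmis),
    removed_high_mito = sum(!passMito),
    thresholds = c(min_genes = minGenes, min_umis = minUmis,
                   max_mito = maxMito)
  )
  out <- sce[, keep]
  S4Vectors::metadata(out)$qc_report <- report
  out
}

#' Library-size log-normalization
#'
#' Computes \code{ln(1 + scaleFactor * count / cellTotal)} and stores it as
#' the \code{logcounts} assay. A zero count maps to 0, so sparsity is
#' preserved.
#'
#' @param sce a SingleCellExperiment with a \code{counts} assay.
#' @param scaleFactor library-size target (default 10,000).
#' @return the SingleCellExperiment with a \code{logcounts} assay added.
#' @export
logNormalize <- function(sce, scaleFactor = 1e4) {
  counts <- SummarizedExperiment::assay(sce, "counts")
  totals <- Matrix::colSums(counts)
  if (any(totals == 0))
    stop("cells with zero total counts cannot be normalized")
  norm <- methods::as(counts, "CsparseMatrix")
  # scale the non-zero entries column-wise, then log1p on the sparse slot
  fac <- scaleFactor / totals
  norm@x <- log1p(norm@x * rep.int(fac, diff(norm@p)))
  SummarizedExperiment::assay(sce, "logcounts") <- norm
  sce
}

#' Select highly variable genes
#'
#' Ranks genes by variance-stabilized dispersion: the variance of the
#' log-normalized expression is regressed on the mean with a loess trend and
#' genes are ranked by their residual above the trend. Ties are broken by
#' gene order, so the selection is deterministic.
#'
#' @param sce a SingleCellExperiment with \code{logcounts}.
#' @param n number of genes to return.
#' @return character vector of gene ids (length \code{n}).
#' @export
selectHvgs <- function(sce, n = 2000) {
  lc <- SummarizedExperiment::assay(sce, "logcounts")
  if (n > nrow(lc))
    stop("n exceeds the number of genes")
  mu <- Matrix::rowMeans(lc)
  m2 <- Matrix::rowMeans(lc^2)
  v <- (m2 - mu^2) * ncol(lc) / max(1, ncol(lc) - 1)
  disp <- v
  ok <- v > 0
  if (sum(ok) > 10) {
    fit <- loess(v[ok] ~ mu[ok], span = 0.5, degree = 2)
    disp[ok] <- v[ok] - predict(fit)
    disp[!ok] <- -Inf
  }
  ord <- order(disp, decreasing = TRUE)
  rownames(lc)[ord[seq_len(n)]]
}

#' Graph-based clustering of cells
#'
#' PCA (centred, \code{nPcs} components) on the selected genes, a shared
#' nearest-neighbor graph, and Leiden community detection under the
#' modularity objective. Deterministic under a fixed seed.
#'
#' @param sce a SingleCellExperiment with \code{logcounts}.
#' @param genes genes to use (defaults to all); typically the HVG set.
#' @param kNeighbors neighbors for the SNN graph.
#' @param resolution modularity resolution.
#' @param nPcs number of principal components.
#' @param seed integer seed.
#' @return integer factor of cluster labels, named by cell.
#' @export
clusterCells <- function(sce, genes = rownames(sce), kNeighbors = 20,
                         resolution = 1.0, nPcs = 50, seed = 1L) {
  lc <- SummarizedExperiment::assay(sce, "logcounts")
  if (ncol(lc) < kNeighbors + 1)
    stop("need at least kNeighbors + 1 cells")
  x <- t(as.matrix(lc[genes, , drop = FALSE]))
  nPcs <- min(nPcs, ncol(x) - 1, nrow(x) - 1)
  set.seed(as.integer(seed %% 2147483647))
  pcs <- irlba::prcomp_irlba(x, n = nPcs, center = TRUE, scale. = FALSE)$x
  g <- scran::buildSNNGraph(pcs, transposed = TRUE, k = kNeighbors,
                            type = "jaccard")
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution, n_iterations = 10)
  labels <- igraph::membership(cl)
  factor(setNames(as.integer(labels), colnames(lc)))
}

# -- Wilcoxon rank-sum machinery ----------------------------------------

# Exact two-sided permutation p-value of the rank-sum statistic under ties,
# by dynamic programming over the distribution of the group-A midrank sum
# across all C(n, nA) assignments. Midranks are doubled to stay integral.
.wilcoxExactP <- function(r2, inA) {
  n <- length(r2)
  nA <- sum(inA)
  maxS <- sum(sort(r2, decreasing = TRUE)[seq_len(nA)])
  # dp[[k]] counts, over subsets of size k, each achievable doubled-rank sum
  dp <- vector("list", nA + 1)
  dp[[1]] <- c(1, numeric(maxS))  # sum = 0 with probability mass 1
  for (k in seq_len(nA)) dp[[k + 1]] <- numeric(maxS + 1)
  for (i in seq_len(n)) {
    ri <- r2[i]
    for (k in rev(seq_len(min(i, nA)))) {
      src <- dp[[k]]
      shifted <- c(numeric(ri), src[seq_len(maxS + 1 - ri)])
      dp[[k + 1]] <- dp[[k + 1]] + shifted
    }
  }
  dist <- dp[[nA + 1]]
  total <- sum(dist)
  obs <- sum(r2[inA])
  mu <- nA * (n + 1)  # doubled scale: E[sum 2*rank] = nA*(n+1)
  devObs <- abs(obs - mu)
  sums <- seq(0, maxS)
  p <- sum(dist[abs(sums - mu) >= devObs - 1e-9]) / total
  min(1, p)
}

# Normal approximation with tie correction and continuity correction,
# matching the classical large-sample rank-sum test.
.wilcoxNormalP <- function(ranks, inA, ties) {
  n <- length(ranks)
  nA <- sum(inA)
  nB <- n - nA
  W <- sum(ranks[inA]) - nA * (nA + 1) / 2  # Mann-Whitney U
  muU <- nA * nB / 2
  tieTerm <- sum(ties^3 - ties)
  sigma2 <- nA * nB / 12 * ((n + 1) - tieTerm / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (abs(W - muU) - 0.5) / sqrt(sigma2)
  min(1, 2 * pnorm(-max(0, z)))
}

.wilcoxP <- function(values, inA, exactMax = 30) {
  ranks <- rank(values)
  nA <- sum(inA)
  nB <- length(values) - nA
  if (nA <= exactMax && nB <= exactMax) {
    .wilcoxExactP(as.integer(round(2 * ranks)), inA)
  } else {
    tab <- table(values)
    .wilcoxNormalP(ranks, inA, as.numeric(tab))
  }
}

#' Wilcoxon rank-sum marker detection
#'
#' For each group (vs all other cells) and each gene, computes detection
#' fractions, the log fold change
#' \code{ln[(mean(expm1(x_in)) + 1) / (mean(expm1(x_out)) + 1)]}, and a
#' two-sided Wilcoxon rank-sum p-value for genes passing the detection and
#' fold-change filters. For small groups (both sides <= 30 cells) the
#' p-value is the exact tied-rank permutation probability; otherwise the
#' tie-corrected normal approximation with continuity correction is used.
#' P-values are BH-adjusted across the tested genes of each group.
#'
#' @param sce SingleCellExperiment with \code{logcounts}, or a plain
#'   genes x cells matrix of log-normalized values.
#' @param groups vector of group labels, one per cell.
#' @param minPct minimum detection fraction in at least one side.
#' @param logfcThreshold minimum absolute log fold change (natural log).
#' @return a \code{DEGTable} data.frame: \code{gene_id}, \code{group},
#'   \code{log_fc}, \code{p}, \code{p_adj}, \code{pct_in}, \code{pct_out},
#'   \code{direction}. Groups with fewer than 3 cells are skipped with a
#'   warning.
#' @export
wilcoxMarkers <- function(sce, groups, minPct = 0.25,
                          logfcThreshold = log(1.5)) {
  lc <- if (methods::is(sce, "SummarizedExperiment"))
    SummarizedExperiment::assay(sce, "logcounts") else sce
  groups <- as.character(groups)
  if (length(groups) != ncol(lc))
    stop("groups must have one label per cell")
  lev <- unique(groups)
  if (length(lev) < 2) stop("at least two groups are required")
  res <- list()
  for (g in lev) {
    inG <- groups == g
    if (sum(inG) < 3) {
      warning("group '", g, "' has fewer than 3 cells; skipped")
      next
    }
    if (sum(!inG) < 3) {
      warning("complement of group '", g, "' has fewer than 3 cells; skipped")
      next
    }
    res[[g]] <- .markersOneGroup(lc, inG, g, minPct, logfcThreshold)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

.markersOneGroup <- function(lc, inG, label, minPct, logfcThreshold) {
  nIn <- sum(inG)
  nOut <- sum(!inG)
  pctIn <- Matrix::rowSums(lc[, inG, drop = FALSE] > 0) / nIn
  pctOut <- Matrix::rowSums(lc[, !inG, drop = FALSE] > 0) / nOut
  # Seurat-style fold change on the de-logged scale with +1 pseudocount
  meanIn <- Matrix::rowSums(expm1(lc[, inG, drop = FALSE])) / nIn
  meanOut <- Matrix::rowSums(expm1(lc[, !inG, drop = FALSE])) / nOut
  logFc <- log((meanIn + 1) / (meanOut + 1))
  tested <- (pmax(pctIn, pctOut) >= minPct) & (abs(logFc) >= logfcThreshold)
  idx <- which(tested)
  if (!length(idx))
    return(data.frame(gene_id = character(0), group = character(0),
                      log_fc = numeric(0), p = numeric(0),
                      p_adj = numeric(0), pct_in = numeric(0),
                      pct_out = numeric(0), direction = character(0)))
  dense <- as.matrix(lc[idx, , drop = FALSE])
  p <- vapply(seq_along(idx), function(i) .wilcoxP(dense[i, ], inG),
              numeric(1))
  data.frame(
    gene_id = rownames(lc)[idx],
    group = label,
    log_fc = logFc[idx],
    p = p,
    p_adj = p.adjust(p, method = "BH"),
    pct_in = pctIn[idx],
    pct_out = pctOut[idx],
    direction = ifelse(logFc[idx] > 0, "up", "down"),
    stringsAsFactors = FALSE
  )
}
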