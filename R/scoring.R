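#' @include AllClasses.R
NULL

.getLogcounts <- function(x) {
  if (methods::is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x, "logcounts")
  else x
}

#' Per-cell module score with expression-matched control genes
#'
#' Genes are binned by their population-average expression into
#' \code{nBins} bins; for each signature gene, \code{nCtrl} control genes
#' are drawn (with replacement) from the gene's bin, and the score of a cell
#' is the mean expression of the signature genes minus the mean expression
#' of the pooled control draw. Adding a constant to all expression values
#' leaves the score unchanged, and a random gene set scores near zero.
#'
#' @param x SingleCellExperiment with \code{logcounts}, or a genes x cells
#'   matrix.
#' @param genes character vector: the gene set.
#' @param nBins number of average-expression bins.
#' @param nCtrl control genes drawn per signature gene.
#' @param seed integer seed for the control draw.
#' @return named numeric vector of per-cell scores.
#' @export
moduleScore <- function(x, genes, nBins = 24, nCtrl = 100, seed = 1L) {
  lc <- .getLogcounts(x)
  genes <- intersect(genes, rownames(lc))
  if (!length(genes)) stop("gene set is entirely absent from the matrix")
  if (nrow(lc) < nBins) stop("need at least nBins genes")
  avg <- Matrix::rowMeans(lc)
  # rank-based binning so bins are (near-)equally filled
  bin <- cut(rank(avg, ties.method = "first"), breaks = nBins,
             labels = FALSE)
  names(bin) <- rownames(lc)
  set.seed(as.integer(seed %% 2147483647))
  ctrl <- unlist(lapply(genes, function(g) {
    pool <- names(bin)[bin == bin[g]]
    pool[sample.int(length(pool), nCtrl, replace = TRUE)]
  }))
  setScore <- Matrix::colMeans(lc[genes, , drop = FALSE])
  ctrlScore <- Matrix::colMeans(lc[ctrl, , drop = FALSE])
  setNames(as.numeric(setScore - ctrlScore), colnames(lc))
}

# deterministic per-cell ranking: descending expression, ties broken by a
# fixed seeded shuffle of gene order
.rankOrder <- function(v, shuffle) {
  order(-v, shuffle)
}

#' Single-sample GSEA-style enrichment score
#'
#' For each cell, genes are ranked by descending expression (ties broken by
#' a fixed seeded shuffle) and the score is the sum over ranks of the
#' difference between the weighted in-set ECDF (weights: expression rank
#' raised to \code{alpha}) and the unweighted out-of-set ECDF. Being purely
#' rank-based, the score is invariant under strictly monotone transforms of
#' a cell's expression vector. With \code{normalize = TRUE} scores are
#' divided by their range across cells.
#'
#' @param x SingleCellExperiment or genes x cells matrix.
#' @param genes the gene set (>= 2 genes after intersection).
#' @param alpha rank-weight exponent.
#' @param normalize divide scores by (max - min) across cells.
#' @param seed seed for the tie-break shuffle.
#' @return named numeric vector of per-cell scores.
#' @export
ssgseaScore <- function(x, genes, alpha = 0.25, normalize = FALSE,
                        seed = 1L) {
  lc <- .getLogcounts(x)
  genes <- intersect(genes, rownames(lc))
  if (length(genes) < 2) stop("gene set must contain at least 2 genes")
  G <- nrow(lc)
  k <- length(genes)
  if (k >= G)
    warning("gene set covers every gene; the out-of-set ECDF is degenerate")
  inSet <- rownames(lc) %in% genes
  set.seed(as.integer(seed %% 2147483647))
  shuffle <- sample.int(G)
  dense <- as.matrix(lc)
  scores <- vapply(seq_len(ncol(dense)), function(j) {
    v <- dense[, j]
    if (length(unique(v)) == 1) {
      warning("cell ", j, " has an all-tie expression vector; score 0")
      return(0)
    }
    ord <- .rankOrder(v, shuffle)
    inOrd <- inSet[ord]
    w <- (G - seq_len(G) + 1)^alpha  # expression rank weight, top-heavy
    wIn <- ifelse(inOrd, w, 0)
    pIn <- cumsum(wIn) / sum(wIn)
    pOut <- if (G > k) cumsum(!inOrd) / (G - k) else rep(1, G)
    sum(pIn - pOut)
  }, numeric(1))
  if (normalize) {
    rng <- max(scores) - min(scores)
    if (rng > 0) scores <- scores / rng
  }
  setNames(scores, colnames(lc))
}

#' AUC-style recovery score
#'
#' For each cell, the recovery curve counts how many gene-set members occur
#' within the top \code{topFrac} fraction of the cell's expression ranking;
#' the score is the area under that curve normalized so that a set occupying
#' the very top ranks scores 1 and a set absent from the window scores 0.
#' The score depends only on the ranking, not on the expression values.
#'
#' @param x SingleCellExperiment or genes x cells matrix.
#' @param genes the gene set.
#' @param topFrac fraction of the ranking forming the recovery window.
#' @param seed seed for the tie-break shuffle.
#' @return named numeric vector of per-cell scores in [0, 1].
#' @export
aucScore <- function(x, genes, topFrac = 0.05, seed = 1L) {
  lc <- .getLogcounts(x)
  genes <- intersect(genes, rownames(lc))
  if (!length(genes)) stop("gene set is entirely absent from the matrix")
  G <- nrow(lc)
  N <- floor(topFrac * G)
  if (N < 2) stop("topFrac * nGenes must be at least 2")
  k <- length(genes)
  inSet <- rownames(lc) %in% genes
  set.seed(as.integer(seed %% 2147483647))
  shuffle <- sample.int(G)
  maxAuc <- sum(pmin(seq_len(N), k))  # all k members at the very top
  dense <- as.matrix(lc)
  scores <- vapply(seq_len(ncol(dense)), function(j) {
    ord <- .rankOrder(dense[, j], shuffle)[seq_len(N)]
    sum(cumsum(inSet[ord])) / maxAuc
  }, numeric(1))
  setNames(scores, colnames(lc))
}

#' Compare per-cell scores between two groups
#'
#' Two-sided Wilcoxon rank-sum test on the scores plus the difference of
#' group medians. Degenerate single-valued input returns p = 1, delta = 0.
#'
#' @param scores numeric vector of per-cell scores.
#' @param groups two-level factor/vector, one label per score.
#' @return list with \code{delta} (median of first level minus median of
#'   second) and \code{p}.
#' @export
compareScores <- function(scores, groups) {
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups are required")
  a <- scores[groups == levels(groups)[1]]
  b <- scores[groups == levels(groups)[2]]
  if (length(a) < 3 || length(b) < 3)
    stop("both groups need at least 3 cells")
  if (length(unique(c(a, b))) == 1)
    return(list(delta = 0, p = 1))
  p <- suppressWarnings(wilcox.test(a, b)$p.value)
  list(delta = median(a) - median(b), p = p)
}
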