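#' @include AllClasses.R AllGenerics.R
NULL

#' Correlation-based candidate expansion
#'
#' Builds the per-cell mean expression of the upregulated DEG set as a
#' signature reference and returns all genes whose Pearson correlation with
#' that reference exceeds \code{rMin}, unioned with the DEG set itself.
#'
#' @param x SingleCellExperiment or genes x cells matrix of log-normalized
#'   values over malignant cells.
#' @param degUp character vector of upregulated DEGs (the seed set).
#' @param rMin correlation threshold.
#' @return character vector of candidate genes.
#' @export
candidateGenes <- function(x, degUp, rMin = 0.5) {
  lc <- .getLogcounts(x)
  degUp <- intersect(degUp, rownames(lc))
  if (!length(degUp)) stop("degUp is empty after intersection")
  ref <- Matrix::colMeans(lc[degUp, , drop = FALSE])
  if (sd(ref) == 0) stop("zero-variance signature reference")
  r <- suppressWarnings(as.numeric(cor(t(as.matrix(lc)), ref)))
  r[is.na(r)] <- 0
  union(degUp, rownames(lc)[r > rMin])
}

#' L1-penalized logistic selection of signature genes
#'
#' Fits a lasso logistic regression of the DGC/PDGC class on the candidate
#' gene expression (\code{alpha = 1}, binomial family), chooses the penalty
#' at the 10-fold cross-validation minimum of the mean deviance, and returns
#' the genes with nonzero coefficients.
#'
#' @param x SingleCellExperiment or genes x cells matrix over malignant
#'   cells.
#' @param candidates genes entering the fit.
#' @param labels two-level class labels, one per cell.
#' @param seed integer seed (controls the CV folds).
#' @param nfolds CV folds.
#' @return list with \code{genes} (nonzero-coefficient genes) and
#'   \code{coefficients} (named numeric, intercept excluded).
#' @export
lassoSelect <- function(x, candidates, labels, seed = 1L, nfolds = 10) {
  lc <- .getLogcounts(x)
  candidates <- intersect(candidates, rownames(lc))
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("labels must have exactly two classes")
  if (min(table(labels)) < 20)
    stop("both classes need at least 20 cells")
  xm <- t(as.matrix(lc[candidates, , drop = FALSE]))
  set.seed(as.integer(seed %% 2147483647))
  fit <- glmnet::cv.glmnet(xm, labels, family = "binomial", alpha = 1,
                           nfolds = nfolds, type.measure = "deviance")
  cf <- as.matrix(stats::coef(fit, s = "lambda.min"))[-1, 1]
  list(genes = names(cf)[cf != 0], coefficients = cf)
}

#' Random-forest importance ranking of signature genes
#'
#' Fits a random-forest classifier of the DGC/PDGC class on the candidate
#' genes and ranks them by mean impurity-decrease importance. Genes in the
#' bottom \code{importanceQuantile} of the importance distribution are
#' flagged as low-contribution.
#'
#' @param x SingleCellExperiment or genes x cells matrix over malignant
#'   cells.
#' @param candidates genes entering the fit.
#' @param labels two-level class labels.
#' @param nTrees,mTry forest size and variables per split (\code{mTry} is
#'   clamped to the candidate count with a warning).
#' @param importanceQuantile quantile below which genes are flagged
#'   low-contribution.
#' @param seed integer seed.
#' @return data.frame ordered by decreasing importance: \code{gene},
#'   \code{importance}, \code{low_contribution}.
#' @export
rfRank <- function(x, candidates, labels, nTrees = 1500, mTry = 10,
                   importanceQuantile = 0.25, seed = 1L) {
  lc <- .getLogcounts(x)
  candidates <- intersect(candidates, rownames(lc))
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("labels must have exactly two classes")
  if (min(table(labels)) < 20)
    stop("both classes need at least 20 cells")
  if (mTry > length(candidates)) {
    warning("mTry exceeds the candidate count; clamped to ",
            length(candidates))
    mTry <- length(candidates)
  }
  xm <- t(as.matrix(lc[candidates, , drop = FALSE]))
  set.seed(as.integer(seed %% 2147483647))
  rf <- randomForest::randomForest(xm, labels, ntree = nTrees, mtry = mTry)
  imp <- rf$importance[, "MeanDecreaseGini"]
  cut <- quantile(imp, importanceQuantile)
  out <- data.frame(gene = names(imp), importance = as.numeric(imp),
                    low_contribution = imp < cut, stringsAsFactors = FALSE)
  out[order(-out$importance), ]
}

#' Derive the tumor-differentiation gene signature
#'
#' Orchestrates the full cascade on malignant cells labelled DGC/PDGC:
#' \enumerate{
#'   \item Wilcoxon markers of DGC vs PDGC; keep significant upregulated
#'     genes (BH-adjusted p below \code{degAlpha}).
#'   \item Expand to genes correlated (> \code{rMin}) with the mean
#'     expression of that DEG set.
#'   \item Keep genes with a nonzero lasso coefficient AND out of the bottom
#'     random-forest importance quartile.
#'   \item Remove the curated exclusion list (prior-knowledge input, never
#'     hard-coded logic).
#'   \item Apply the expression floor: mean log-normalized expression in DGC
#'     malignant cells must exceed \code{ln(1 + 0.5)}; with
#'     \code{literalFloor = TRUE} the threshold is \code{ln(0.5)} instead
#'     (vacuous on non-negative data, provided for comparability).
#' }
#'
#' @param x SingleCellExperiment or genes x cells log-normalized matrix of
#'   malignant cells only.
#' @param labels per-cell pathology labels, "DGC" or "PDGC".
#' @param exclusionList curated genes removed regardless of statistics.
#' @param rMin correlation threshold of stage 2.
#' @param degAlpha BH-adjusted significance threshold of stage 1.
#' @param nTrees,mTry,importanceQuantile random-forest stage parameters.
#' @param literalFloor use ln(0.5) as the floor instead of ln(1.5).
#' @param seed integer seed.
#' @return a [GeneSignature-class] with full per-candidate provenance.
#' @export
deriveSignature <- function(x, labels,
                            exclusionList = c("TM4SF20", "HEPH", "LINC01133",
                                              "PPP1R1B", "AKR1C3", "REEP6"),
                            rMin = 0.5, degAlpha = 0.05,
                            nTrees = 1500, mTry = 10,
                            importanceQuantile = 0.25,
                            literalFloor = FALSE, seed = 1L) {
  lc <- .getLogcounts(x)
  labels <- as.character(labels)
  if (!all(labels %in% c("DGC", "PDGC")))
    stop("labels must be DGC or PDGC")

  deg <- wilcoxMarkers(lc, labels)
  degUp <- deg$gene_id[deg$group == "DGC" & deg$direction == "up" &
                         deg$p_adj < degAlpha]
  if (!length(degUp))
    stop("signature cascade failed at stage 'deg': no upregulated DGC genes")

  cand <- candidateGenes(lc, degUp, rMin = rMin)
  if (!length(cand))
    stop("signature cascade failed at stage 'correlation'")

  las <- lassoSelect(lc, cand, labels, seed = seed)
  if (!length(las$genes))
    stop("signature cascade failed at stage 'lasso': all coefficients zero")

  rf <- rfRank(lc, cand, labels, nTrees = nTrees, mTry = mTry,
               importanceQuantile = importanceQuantile, seed = seed)
  rfKept <- rf$gene[!rf$low_contribution]

  kept <- intersect(las$genes, rfKept)
  if (!length(kept))
    stop("signature cascade failed at stage 'random_forest'")

  floorCut <- if (literalFloor) log(0.5) else log1p(0.5)
  dgcMean <- Matrix::rowMeans(lc[cand, labels == "DGC", drop = FALSE])

  pv <- data.frame(
    gene = cand,
    deg_up = cand %in% degUp,
    corr_candidate = TRUE,
    lasso_kept = cand %in% las$genes,
    rf_kept = cand %in% rfKept,
    excluded = cand %in% exclusionList,
    floor_failed = as.numeric(dgcMean[cand]) <= floorCut,
    stringsAsFactors = FALSE
  )
  final <- pv$gene[pv$lasso_kept & pv$rf_kept & !pv$excluded &
                     !pv$floor_failed]
  if (!length(final))
    stop("signature cascade failed at stage 'floor': no genes survive")
  pv$in_signature <- pv$gene %in% final
  # order the signature by RF importance
  final <- rf$gene[rf$gene %in% final]

  methods::new("GeneSignature",
               name = "tumor_differentiation",
               genes = final,
               provenance = pv,
               params = list(rMin = rMin, degAlpha = degAlpha,
                             nTrees = nTrees, mTry = mTry,
                             importanceQuantile = importanceQuantile,
                             literalFloor = literalFloor,
                             exclusionList = exclusionList, seed = seed))
}

#' Tumor score, differentiation score and their correlation
#'
#' The tumor score is the module score of the genes upregulated in malignant
#' vs non-malignant epithelial cells; the differentiation score is the
#' module score of the signature genes; \code{r} is their Pearson
#' correlation across malignant cells.
#'
#' @param x SingleCellExperiment or genes x cells log-normalized matrix of
#'   epithelial cells.
#' @param malignant logical vector: which of those cells are malignant.
#' @param signature a [GeneSignature-class] or character vector of genes.
#' @param degAlpha significance threshold for the tumor up-DEGs.
#' @param seed integer seed (module-score controls).
#' @return list with \code{tumor} and \code{diff} (named score vectors over
#'   all cells), \code{r} (correlation over malignant cells) and
#'   \code{tumor_genes}.
#' @export
tumorDiffScores <- function(x, malignant, signature, degAlpha = 0.05,
                            seed = 1L) {
  lc <- .getLogcounts(x)
  if (length(malignant) != ncol(lc))
    stop("malignant must have one entry per cell")
  sig <- if (methods::is(signature, "GeneSignature"))
    signatureGenes(signature) else signature
  grp <- ifelse(malignant, "malignant", "non_malignant")
  deg <- wilcoxMarkers(lc, grp)
  tumorUp <- deg$gene_id[deg$group == "malignant" & deg$direction == "up" &
                           deg$p_adj < degAlpha]
  if (!length(tumorUp)) stop("no upregulated malignant DEGs found")
  tumor <- moduleScore(lc, tumorUp, seed = seed)
  diffS <- moduleScore(lc, sig, seed = seed + 1)
  r <- cor(tumor[malignant], diffS[malignant])
  list(tumor = tumor, diff = diffS, r = r, tumor_genes = tumorUp)
}

#' Overlap between two gene sets
#'
#' Jaccard index and one-sided hypergeometric enrichment p-value of the
#' observed intersection given a universe size.
#'
#' @param a,b character gene sets.
#' @param universe integer universe size (>= size of the union).
#' @return data.frame: set sizes, intersection, jaccard, p_hyper, universe.
#' @export
signatureOverlap <- function(a, b, universe) {
  a <- unique(a); b <- unique(b)
  if (!length(a) || !length(b)) stop("empty gene set")
  if (universe < length(union(a, b)))
    stop("universe smaller than the union of the sets")
  inter <- length(intersect(a, b))
  jac <- inter / length(union(a, b))
  p <- phyper(inter - 1, length(a), universe - length(a), length(b),
              lower.tail = FALSE)
  data.frame(size_a = length(a), size_b = length(b), intersection = inter,
             jaccard = jac, p_hyper = p, universe = universe)
}
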