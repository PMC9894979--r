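#' @include AllClasses.R AllGenerics.R
NULL

#' PCA-based trans-differentiation pseudotime
#'
#' Runs PCA on the epithelial cells, places a piecewise-linear path through
#' the centroids of the non-malignant, DGC-malignant and NEC cells, projects
#' every cell onto the path and returns the normalized arc-length of the
#' projection as pseudotime: non-malignant anchor at 0, NEC anchor at 1,
#' with the DGC anchor at its arc-length position between them. Intermediate
#' cells receive no anchor and fall where their projection places them.
#'
#' @param x SingleCellExperiment or genes x cells log-normalized matrix of
#'   epithelial cells.
#' @param anchors character vector (one per cell) with values
#'   \code{"non_malignant"}, \code{"DGC"}, \code{"NEC"} or NA for
#'   unanchored cells.
#' @param nPcs number of principal components.
#' @param seed integer seed (PCA initialization).
#' @return a [PseudotimePath-class].
#' @export
pseudotimePath <- function(x, anchors, nPcs = 30, seed = 1L) {
  lc <- .getLogcounts(x)
  if (length(anchors) != ncol(lc))
    stop("anchors must have one entry per cell")
  need <- c("non_malignant", "DGC", "NEC")
  if (!all(need %in% anchors))
    stop("anchor classes non_malignant, DGC and NEC must all be present")
  if (ncol(lc) < 50) stop("at least 50 cells are required")
  xm <- t(as.matrix(lc))
  nPcs <- min(nPcs, ncol(xm) - 1, nrow(xm) - 1)
  set.seed(as.integer(seed %% 2147483647))
  pc <- irlba::prcomp_irlba(xm, n = nPcs, center = TRUE, scale. = FALSE)
  emb <- pc$x
  rownames(emb) <- colnames(lc)

  cent <- t(vapply(need, function(a)
    colMeans(emb[which(anchors == a), , drop = FALSE]), numeric(nPcs)))
  seg1 <- sqrt(sum((cent["DGC", ] - cent["non_malignant", ])^2))
  seg2 <- sqrt(sum((cent["NEC", ] - cent["DGC", ])^2))
  total <- seg1 + seg2
  if (total == 0) stop("anchor centroids coincide")

  # project each cell onto the two segments, keep the nearer projection
  proj <- vapply(seq_len(nrow(emb)), function(i) {
    p <- emb[i, ]
    best <- c(Inf, 0)
    offs <- c(0, seg1)
    starts <- list(cent["non_malignant", ], cent["DGC", ])
    ends <- list(cent["DGC", ], cent["NEC", ])
    lens <- c(seg1, seg2)
    for (s in 1:2) {
      v <- ends[[s]] - starts[[s]]
      tt <- if (lens[s] > 0)
        min(1, max(0, sum((p - starts[[s]]) * v) / lens[s]^2)) else 0
      q <- starts[[s]] + tt * v
      d <- sum((p - q)^2)
      if (d < best[1]) best <- c(d, offs[s] + tt * lens[s])
    }
    best[2] / total
  }, numeric(1))
  names(proj) <- rownames(emb)

  # orientation guard: DGC cells must average below NEC cells
  if (mean(proj[anchors == "DGC"], na.rm = TRUE) >
      mean(proj[anchors == "NEC"], na.rm = TRUE))
    proj <- 1 - proj

  methods::new("PseudotimePath",
               pseudotime = proj,
               anchors = cent,
               waypoints = c(non_malignant = 0, DGC = seg1 / total, NEC = 1),
               rotation = pc$rotation,
               center = pc$center)
}

#' Genes changing monotonically along the pseudotime path
#'
#' Spearman correlation of every gene with pseudotime, BH-adjusted p-values
#' (t approximation), and the signed report of genes with
#' \code{|rho| >= rhoMin} at \code{FDR <= fdr}. Constant genes are skipped
#' and recorded.
#'
#' @param x SingleCellExperiment or genes x cells log-normalized matrix of
#'   the same cells the path was built on.
#' @param path a [PseudotimePath-class] (or numeric pseudotime vector).
#' @param rhoMin minimum absolute Spearman correlation.
#' @param fdr BH false-discovery threshold.
#' @return list with \code{trends} (data.frame: gene, rho, p, p_adj,
#'   direction, significant) and \code{skipped} (constant genes).
#' @export
monotoneGenes <- function(x, path, rhoMin = 0.3, fdr = 0.05) {
  lc <- .getLogcounts(x)
  ptime <- if (methods::is(path, "PseudotimePath")) pseudotimes(path) else path
  if (length(ptime) != ncol(lc))
    stop("pseudotime must cover every cell of the matrix")
  dense <- as.matrix(lc)
  const <- apply(dense, 1, function(v) length(unique(v)) == 1)
  skipped <- rownames(dense)[const]
  dense <- dense[!const, , drop = FALSE]
  n <- length(ptime)
  rt <- rank(ptime)
  rho <- as.numeric(cor(apply(dense, 1, rank), rt))  # apply yields cells x genes
  # t approximation for the Spearman null
  tstat <- rho * sqrt((n - 2) / pmax(1e-12, 1 - rho^2))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  padj <- p.adjust(p, method = "BH")
  trends <- data.frame(
    gene = rownames(dense), rho = rho, p = p, p_adj = padj,
    direction = ifelse(rho > 0, "up", "down"),
    significant = abs(rho) >= rhoMin & padj <= fdr,
    stringsAsFactors = FALSE
  )
  list(trends = trends[order(-abs(trends$rho)), ], skipped = skipped)
}
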