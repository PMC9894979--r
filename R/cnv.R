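#' @include AllClasses.R AllGenerics.R
NULL

#' Windowed genomic smoothing of expression
#'
#' Builds the cells x windows relative-expression matrix used for
#' expression-inferred CNV profiling. Genes are restricted to those expressed
#' in at least \code{minCellsExpr} cells, ordered along the genome, each
#' cell's values are centred by its own mean, and non-overlapping windows of
#' \code{winSize} consecutive genes are averaged per chromosome (a trailing
#' window keeps the remainder genes). Chromosomes with fewer than
#' \code{winSize} usable genes are dropped with a warning; mitochondrial
#' genes are never used.
#'
#' @param sce SingleCellExperiment with \code{logcounts} and positional
#'   \code{rowData} (\code{chrom}, \code{start}, \code{end},
#'   \code{is_mitochondrial}).
#' @param winSize genes per window.
#' @param minCellsExpr minimum number of cells expressing a gene.
#' @return a [CnvProfile-class] (no baseline yet).
#' @export
smoothGenomic <- function(sce, winSize = 25, minCellsExpr = 10) {
  lc <- SummarizedExperiment::assay(sce, "logcounts")
  ann <- as.data.frame(SummarizedExperiment::rowData(sce))
  if ("start_bp" %in% colnames(ann)) {
    names(ann)[names(ann) == "start_bp"] <- "start"
    names(ann)[names(ann) == "end_bp"] <- "end"
  }
  expressed <- Matrix::rowSums(lc > 0) >= minCellsExpr
  usable <- expressed & !ann$is_mitochondrial & !is.na(ann$chrom) &
    ann$chrom != "MT"
  ann <- ann[usable, , drop = FALSE]
  lc <- lc[usable, , drop = FALSE]
  ord <- order(ann$chrom, ann$start)
  ann <- ann[ord, , drop = FALSE]
  lc <- lc[ord, , drop = FALSE]

  keepChrom <- names(which(table(ann$chrom) >= winSize))
  dropped <- setdiff(unique(ann$chrom), keepChrom)
  if (length(dropped))
    warning("chromosome(s) with fewer than ", winSize, " genes dropped: ",
            paste(dropped, collapse = ", "))
  if (!length(keepChrom))
    stop("no chromosome has at least winSize usable genes")
  keep <- ann$chrom %in% keepChrom
  ann <- ann[keep, , drop = FALSE]
  x <- t(as.matrix(lc[keep, , drop = FALSE]))  # cells x genes
  x <- x - rowMeans(x)                          # centre each cell

  winList <- list()
  mats <- list()
  for (ch in keepChrom) {
    idx <- which(ann$chrom == ch)
    nW <- floor(length(idx) / winSize)
    starts <- (seq_len(nW) - 1) * winSize + 1
    ends <- starts + winSize - 1
    ends[nW] <- length(idx)  # trailing remainder joins... see below
    # trailing remainder forms its own window when >= 1 gene is left over
    if (length(idx) %% winSize > 0) {
      ends[nW] <- nW * winSize
      starts <- c(starts, nW * winSize + 1)
      ends <- c(ends, length(idx))
      nW <- nW + 1
    }
    wm <- vapply(seq_len(nW), function(w) {
      cols <- idx[starts[w]:ends[w]]
      rowMeans(x[, cols, drop = FALSE])
    }, numeric(nrow(x)))
    mats[[ch]] <- wm
    winList[[ch]] <- data.frame(
      chrom = ch,
      start = vapply(seq_len(nW), function(w) min(ann$start[idx[starts[w]:ends[w]]]), numeric(1)),
      end = vapply(seq_len(nW), function(w) max(ann$end[idx[starts[w]:ends[w]]]), numeric(1)),
      n_genes = ends - starts + 1
    )
  }
  mat <- do.call(cbind, mats)
  windows <- do.call(rbind, winList)
  rownames(windows) <- NULL
  colnames(mat) <- sprintf("%s_w%03d", windows$chrom,
                           unlist(lapply(winList, function(w) seq_len(nrow(w)))))
  rownames(mat) <- colnames(lc)
  methods::new("CnvProfile", windows = windows, matrix = mat)
}

#' Baseline subtraction and the CNV deviation score
#'
#' Subtracts the mean window profile of the designated normal cells from
#' every cell's profile and computes each cell's deviation score: the mean
#' over windows of the squared baseline-subtracted values. Normal cells
#' therefore score near zero and aneuploid cells score in proportion to the
#' span and amplitude of their copy-number alterations.
#'
#' @param profile a [CnvProfile-class] from [smoothGenomic()].
#' @param normalMask logical vector (one per cell): the reference normal
#'   epithelial cells.
#' @return the profile with baseline subtracted and deviation filled.
#' @export
cnvDeviation <- function(profile, normalMask) {
  stopifnot(methods::is(profile, "CnvProfile"))
  m <- profile@matrix
  if (length(normalMask) != nrow(m))
    stop("normalMask must have one entry per cell")
  if (!any(normalMask)) stop("normalMask selects no cells")
  if (sum(normalMask) < 20)
    warning("fewer than 20 normal reference cells; baseline will be noisy")
  baseline <- colMeans(m[normalMask, , drop = FALSE])
  m <- sweep(m, 2, baseline)
  methods::new("CnvProfile", windows = profile@windows, matrix = m,
               baseline = baseline, deviation = rowMeans(m^2),
               baselined = TRUE)
}

#' Classify epithelial clusters as malignant or non-malignant
#'
#' Applies the three-step logic combining CNV level with cluster
#' composition: a cluster is called malignant iff its median deviation
#' exceeds \code{devRatio} times the median deviation of normal-mucosa cells
#' AND fewer than \code{maxNormalMix} of its member cells come from the
#' normal mucosa sample (non-malignant epithelial cells from different
#' samples cluster together with normal mucosa; malignant cells do not).
#'
#' If no normal-mucosa cells are present the reference median falls back to
#' the median deviation of all cells (flagged in the result); with
#' \code{requireNormal = TRUE} this situation is an error instead.
#'
#' @param profile a baselined [CnvProfile-class] with deviation scores.
#' @param clusters cluster labels for the profiled cells.
#' @param normalCells logical (or character vector of cell ids): which
#'   profiled cells are from normal mucosa.
#' @param devRatio deviation-ratio threshold.
#' @param maxNormalMix maximum tolerated fraction of normal-mucosa cells in
#'   a malignant cluster.
#' @param requireNormal error instead of falling back when no normal-mucosa
#'   cells exist.
#' @return list with \code{calls} (per-cluster data.frame: cluster, call,
#'   median_deviation, normal_fraction, separation), \code{malignant} (named
#'   logical per cell) and \code{fallback} (logical).
#' @export
classifyMalignant <- function(profile, clusters, normalCells,
                              devRatio = 3.0, maxNormalMix = 0.1,
                              requireNormal = FALSE) {
  stopifnot(methods::is(profile, "CnvProfile"))
  dev <- deviationScores(profile)
  cells <- names(dev)
  if (is.character(normalCells)) normalCells <- cells %in% normalCells
  if (length(normalCells) != length(cells))
    stop("normalCells must match the profiled cells")
  clusters <- as.character(clusters)
  if (length(clusters) != length(cells))
    stop("clusters must match the profiled cells")

  fallback <- !any(normalCells)
  if (fallback) {
    if (requireNormal)
      stop("no normal-mucosa cells present; cannot anchor the CNV baseline")
    warning("no normal-mucosa cells present; ",
            "using the overall median deviation as reference")
    ref <- median(dev)
  } else {
    ref <- median(dev[normalCells])
  }
  ref <- max(ref, .Machine$double.eps)

  calls <- do.call(rbind, lapply(unique(clusters), function(cl) {
    inCl <- clusters == cl
    md <- median(dev[inCl])
    nf <- mean(normalCells[inCl])
    sep <- md > devRatio * ref
    data.frame(cluster = cl, call = if (sep && nf < maxNormalMix)
      "malignant" else "non-malignant",
      median_deviation = md, normal_fraction = nf, separation = sep,
      stringsAsFactors = FALSE)
  }))
  malig <- setNames(calls$call[match(clusters, calls$cluster)] == "malignant",
                    cells)
  list(calls = calls, malignant = malig, fallback = fallback)
}
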