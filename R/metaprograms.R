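#' @include AllClasses.R AllGenerics.R
NULL

#' Non-negative input for expression NMF
#'
#' Builds the standard non-negative cells x genes input for expression-based
#' program discovery: log-normalized expression of the selected genes,
#' centred per gene and clipped at zero (the positive residual). Centring
#' removes the shared baseline so factors describe programs rather than
#' absolute expression.
#'
#' @param x SingleCellExperiment with \code{logcounts} or a genes x cells
#'   matrix.
#' @param genes genes to use (typically HVGs).
#' @return non-negative numeric matrix, cells x genes.
#' @export
nmfInput <- function(x, genes = NULL) {
  lc <- .getLogcounts(x)
  if (!is.null(genes)) lc <- lc[intersect(genes, rownames(lc)), ,
                                drop = FALSE]
  v <- t(as.matrix(lc))
  pmax(sweep(v, 2, colMeans(v)), 0)
}

#' Non-negative matrix factorization by multiplicative updates
#'
#' Factorizes a non-negative cells x genes matrix \code{V} into
#' \code{usage \%*\% t(loadings)} (usage: cells x k, loadings: genes x k)
#' by Lee-Seung multiplicative updates minimizing squared reconstruction
#' error. The objective is non-increasing across iterations; iteration stops
#' when the relative decrease of the error falls below \code{tol} or after
#' \code{maxIter} iterations. Deterministic under a fixed seed (random
#' uniform initialization).
#'
#' @param v non-negative matrix, cells x genes (e.g. log-normalized HVG
#'   expression of one sample's malignant cells, or an AUC score matrix).
#' @param k number of factors.
#' @param seed integer seed.
#' @param maxIter,tol stopping rule.
#' @return list with \code{loadings} (genes x k), \code{usage} (cells x k),
#'   \code{error} (trajectory of the relative Frobenius error) and
#'   \code{iterations}.
#' @export
nmfFactorize <- function(v, k = 10, seed = 1L, maxIter = 500, tol = 1e-5) {
  v <- as.matrix(v)
  if (any(v < 0)) stop("input must be non-negative")
  n <- nrow(v); m <- ncol(v)
  if (n < k || m < k) stop("need at least k cells and k genes")
  set.seed(as.integer(seed %% 2147483647))
  w <- matrix(runif(n * k, 0.1, 1), n, k)  # usage
  h <- matrix(runif(k * m, 0.1, 1), k, m)  # t(loadings)
  eps <- 1e-12
  vNorm <- sqrt(sum(v^2))
  errs <- numeric(0)
  last <- Inf
  it <- 0
  while (it < maxIter) {
    it <- it + 1
    h <- h * (crossprod(w, v) / (crossprod(w) %*% h + eps))
    w <- w * (v %*% t(h)) / (w %*% tcrossprod(h) + eps)
    err <- sqrt(sum((v - w %*% h)^2)) / vNorm
    errs <- c(errs, err)
    if (is.finite(last) && (last - err) < tol * max(last, eps)) break
    last <- err
  }
  loadings <- t(h)
  colnames(loadings) <- colnames(w) <- paste0("factor", seq_len(k))
  rownames(loadings) <- colnames(v)
  rownames(w) <- rownames(v)
  list(loadings = loadings, usage = w, error = errs, iterations = it)
}

#' Cluster NMF factors across samples into shared programs
#'
#' Computes Pearson correlations between the gene-loading vectors of all
#' factors (restricted to the genes shared across samples), clusters factors
#' by average linkage on (1 - r), cuts the tree at \code{cutHeight}, and
#' retains as programs the clusters containing factors from at least
#' \code{minSamples} distinct samples. Program gene lists are the
#' \code{topM} genes by mean loading rank across the program's factors.
#'
#' @param factorList named list (one element per sample) of genes x k
#'   loading matrices, as returned by [nmfFactorize()]\code{$loadings}.
#' @param topM program gene list size.
#' @param minSamples minimum number of distinct samples per program.
#' @param cutHeight tree cut height on the (1 - r) scale.
#' @return a [ProgramSet-class].
#' @export
clusterFactors <- function(factorList, topM = 50, minSamples = 2,
                           cutHeight = 0.6) {
  if (length(factorList) < 2)
    stop("factors from at least two samples are required")
  if (is.null(names(factorList)))
    names(factorList) <- paste0("sample", seq_along(factorList))
  shared <- Reduce(intersect, lapply(factorList, rownames))
  if (!length(shared)) stop("no genes shared across samples")
  mats <- lapply(names(factorList), function(s) {
    m <- factorList[[s]][shared, , drop = FALSE]
    colnames(m) <- paste0(s, ".", colnames(m))
    m
  })
  names(mats) <- names(factorList)
  all <- do.call(cbind, mats)
  sampleOf <- rep(names(factorList),
                  vapply(mats, ncol, integer(1)))
  names(sampleOf) <- colnames(all)

  r <- suppressWarnings(cor(all))
  r[is.na(r)] <- 0
  diag(r) <- 1
  r <- (r + t(r)) / 2

  hc <- hclust(as.dist(1 - r), method = "average")
  grp <- cutree(hc, h = cutHeight)

  assignments <- data.frame(
    factor = colnames(all),
    sample = as.character(sampleOf),
    program = NA_character_,
    stringsAsFactors = FALSE
  )
  progGenes <- list()
  pId <- 0
  for (g in sort(unique(grp))) {
    members <- names(grp)[grp == g]
    if (length(unique(sampleOf[members])) < minSamples) next
    pId <- pId + 1
    pname <- paste0("program", pId)
    assignments$program[assignments$factor %in% members] <- pname
    rk <- vapply(members, function(f)
      rank(-all[, f], ties.method = "average"), numeric(length(shared)))
    meanRank <- rowMeans(rk)
    progGenes[[pname]] <- shared[order(meanRank)][seq_len(min(topM,
                                                              length(shared)))]
  }

  methods::new("ProgramSet",
               factors = mats,
               correlation = r,
               assignments = assignments,
               program_genes = progGenes,
               tree = list(merge = hc$merge, height = hc$height,
                           order = hc$order, labels = hc$labels))
}
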