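#' @import methods
#' @importFrom stats median quantile cor var sd rnbinom rlnorm runif rbinom
#'   rexp rnorm p.adjust phyper pnorm setNames loess predict prcomp cutree
#'   hclust as.dist cor.test wilcox.test rmultinom pt
#' @importFrom utils head read.delim write.table
NULL

#' CnvProfile: smoothed genomic expression profile with per-cell deviation
#'
#' Holds the windowed, cell-centred relative-expression matrix produced by
#' [smoothGenomic()], the diploid baseline estimated from normal mucosa cells
#' by [cnvDeviation()], and the per-cell CNV deviation score (the mean of
#' squared baseline-subtracted window values).
#'
#' @slot windows data.frame with one row per genomic window: \code{chrom},
#'   \code{start}, \code{end} (bp, from member genes), \code{n_genes}.
#' @slot matrix numeric matrix, cells x windows. Before baseline subtraction
#'   these are cell-centred window means; afterwards they are relative to the
#'   normal-cell baseline.
#' @slot baseline numeric vector of per-window baseline values (length 0 until
#'   [cnvDeviation()] is run).
#' @slot deviation numeric vector of per-cell deviation scores (length 0 until
#'   [cnvDeviation()] is run).
#' @slot baselined logical; has the baseline been subtracted?
#'
#' @export
setClass("CnvProfile",
  representation(
    windows = "data.frame",
    matrix = "matrix",
    baseline = "numeric",
    deviation = "numeric",
    baselined = "logical"
  ),
  prototype(
    baseline = numeric(0), deviation = numeric(0), baselined = FALSE
  )
)

setValidity("CnvProfile", function(object) {
  msg <- NULL
  if (nrow(object@windows) != ncol(object@matrix))
    msg <- c(msg, "number of windows must match matrix columns")
  if (length(object@baseline) &&
      length(object@baseline) != ncol(object@matrix))
    msg <- c(msg, "baseline length must match number of windows")
  if (length(object@deviation)) {
    if (length(object@deviation) != nrow(object@matrix))
      msg <- c(msg, "deviation length must match number of cells")
    if (any(object@deviation < -1e-12))
      msg <- c(msg, "deviation scores must be non-negative")
    # the deviation slot must be re-derivable from the matrix
    chk <- rowMeans(object@matrix^2)
    if (max(abs(chk - object@deviation)) > 1e-8)
      msg <- c(msg, "deviation must equal the row mean of squared entries")
  }
  if (!all(c("chrom", "start", "end", "n_genes") %in% colnames(object@windows)))
    msg <- c(msg, "windows must have chrom/start/end/n_genes columns")
  if (is.null(msg)) TRUE else msg
})

#' GeneSignature: an ordered gene list with per-gene provenance
#'
#' The result of the differentiation-signature derivation cascade. Every
#' candidate gene that entered the cascade carries flags recording how far it
#' travelled: upregulated DEG, correlation candidate, kept by the lasso, kept
#' by the random forest, removed by the curated exclusion list, or removed by
#' the expression floor.
#'
#' @slot name character scalar.
#' @slot genes character vector: the final signature, ordered by random-forest
#'   importance.
#' @slot provenance data.frame with one row per candidate gene and logical
#'   columns \code{deg_up}, \code{corr_candidate}, \code{lasso_kept},
#'   \code{rf_kept}, \code{excluded}, \code{floor_failed}, plus
#'   \code{in_signature}.
#' @slot params list: parameter snapshot of the run.
#'
#' @export
setClass("GeneSignature",
  representation(
    name = "character",
    genes = "character",
    provenance = "data.frame",
    params = "list"
  )
)

setValidity("GeneSignature", function(object) {
  msg <- NULL
  req <- c("gene", "deg_up", "corr_candidate", "lasso_kept", "rf_kept",
           "excluded", "floor_failed", "in_signature")
  if (!all(req %in% colnames(object@provenance)))
    msg <- c(msg, "provenance is missing required flag columns")
  if (length(object@genes)) {
    pv <- object@provenance
    fin <- pv[pv$gene %in% object@genes, , drop = FALSE]
    if (!all(object@genes %in% pv$gene))
      msg <- c(msg, "all signature genes must appear in provenance")
    else if (!all(fin$lasso_kept & fin$rf_kept & !fin$excluded &
                  !fin$floor_failed))
      msg <- c(msg,
        "signature genes must be lasso_kept & rf_kept & !excluded & !floor_failed")
  }
  if (anyDuplicated(object@genes))
    msg <- c(msg, "signature genes must be unique")
  if (is.null(msg)) TRUE else msg
})

#' ProgramSet: cross-sample NMF meta-programs
#'
#' Per-sample NMF factor loadings together with the factor-factor Pearson
#' correlation matrix, the average-linkage clustering of factors, and the
#' resulting shared transcriptomic programs.
#'
#' @slot factors named list (one element per sample) of gene x k loading
#'   matrices restricted to the shared gene space.
#' @slot correlation symmetric factor-factor Pearson correlation matrix.
#' @slot assignments data.frame: \code{factor}, \code{sample},
#'   \code{program} (NA for factors not in any retained program).
#' @slot program_genes named list of character vectors (top loadings by mean
#'   rank within each program).
#' @slot tree the \code{hclust} tree over factors (as a list to keep the slot
#'   class simple).
#'
#' @export
setClass("ProgramSet",
  representation(
    factors = "list",
    correlation = "matrix",
    assignments = "data.frame",
    program_genes = "list",
    tree = "list"
  )
)

setValidity("ProgramSet", function(object) {
  msg <- NULL
  r <- object@correlation
  if (nrow(r) != ncol(r)) msg <- c(msg, "correlation matrix must be square")
  else {
    if (max(abs(r - t(r))) > 1e-8)
      msg <- c(msg, "correlation matrix must be symmetric")
    if (nrow(r) > 0 && max(abs(diag(r) - 1)) > 1e-8)
      msg <- c(msg, "correlation matrix must have unit diagonal")
  }
  if (nrow(object@assignments) != nrow(r))
    msg <- c(msg, "one assignment row per factor required")
  if (is.null(msg)) TRUE else msg
})

#' PseudotimePath: PCA-based trans-differentiation pseudotime
#'
#' A piecewise-linear path through the non-malignant, differentiated-cancer
#' and neuroendocrine-cancer anchor centroids in PCA space, and each
#' epithelial cell's normalized arc-length position along it.
#'
#' @slot pseudotime named numeric in [0, 1], one value per epithelial cell.
#' @slot anchors numeric matrix (3 x n_pcs): the anchor centroids in PCA
#'   space, rows named \code{non_malignant}, \code{DGC}, \code{NEC}.
#' @slot waypoints numeric vector: arc-length positions (in [0, 1]) of the
#'   three anchors along the path.
#' @slot rotation gene loadings of the PCA (genes x n_pcs), kept so the path
#'   is defined in a reproducible coordinate frame.
#' @slot center numeric vector of gene means used for the PCA projection.
#'
#' @export
setClass("PseudotimePath",
  representation(
    pseudotime = "numeric",
    anchors = "matrix",
    waypoints = "numeric",
    rotation = "matrix",
    center = "numeric"
  )
)

setValidity("PseudotimePath", function(object) {
  msg <- NULL
  pt <- object@pseudotime
  if (length(pt) && (min(pt) < -1e-9 || max(pt) > 1 + 1e-9))
    msg <- c(msg, "pseudotime values must lie in [0, 1]")
  if (nrow(object@anchors) != 3)
    msg <- c(msg, "exactly three anchor centroids are required")
  if (length(object@waypoints) != 3)
    msg <- c(msg, "exactly three waypoint positions are required")
  if (is.null(msg)) TRUE else msg
})
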