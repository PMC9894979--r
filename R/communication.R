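#' @include AllClasses.R
NULL

#' Extract ligand-receptor edges between cell types
#'
#' For every ligand-receptor pair and every ordered (sender, receiver) cell
#' type combination, an edge is kept iff the ligand is detected (nonzero) in
#' at least \code{detect} of the sender cells AND the receptor in at least
#' \code{detect} of the receiver cells. The edge weight is the mean ligand
#' expression in the sender times the mean receptor expression in the
#' receiver (the mean method); the specificity is the sender's share of the
#' ligand mean across all types times the receiver's share of the receptor
#' mean.
#'
#' @param x SingleCellExperiment or genes x cells log-normalized matrix.
#' @param types cell-type labels, one per cell.
#' @param pairs data.frame with columns \code{ligand} and \code{receptor}.
#' @param detect detection-fraction threshold.
#' @return EdgeTable data.frame: sender, receiver, ligand, receptor, weight,
#'   ligand_detect_frac, receptor_detect_frac, specificity.
#' @export
extractEdges <- function(x, types, pairs, detect = 0.2) {
  lc <- .getLogcounts(x)
  if (!nrow(pairs)) stop("empty ligand-receptor pair list")
  if (!all(c("ligand", "receptor") %in% colnames(pairs)))
    stop("pairs must have ligand and receptor columns")
  types <- as.character(types)
  if (length(types) != ncol(lc)) stop("types must have one label per cell")
  tl <- unique(types)
  if (length(tl) < 2) stop("at least two cell types are required")
  pairs <- pairs[pairs$ligand %in% rownames(lc) &
                   pairs$receptor %in% rownames(lc), , drop = FALSE]
  if (!nrow(pairs)) stop("no pair references genes of the matrix")

  usedGenes <- unique(c(pairs$ligand, pairs$receptor))
  sub <- as.matrix(lc[usedGenes, , drop = FALSE])
  meanBy <- vapply(tl, function(ty)
    rowMeans(sub[, types == ty, drop = FALSE]), numeric(nrow(sub)))
  detBy <- vapply(tl, function(ty)
    rowMeans(sub[, types == ty, drop = FALSE] > 0), numeric(nrow(sub)))
  rownames(meanBy) <- rownames(detBy) <- usedGenes
  totalMean <- rowSums(meanBy)

  grid <- expand.grid(sender = tl, receiver = tl, pair = seq_len(nrow(pairs)),
                      stringsAsFactors = FALSE)
  lig <- pairs$ligand[grid$pair]
  rec <- pairs$receptor[grid$pair]
  ldet <- detBy[cbind(lig, grid$sender)]
  rdet <- detBy[cbind(rec, grid$receiver)]
  keep <- ldet >= detect & rdet >= detect
  lm <- meanBy[cbind(lig, grid$sender)]
  rm_ <- meanBy[cbind(rec, grid$receiver)]
  spec <- ifelse(totalMean[lig] > 0, lm / totalMean[lig], 0) *
    ifelse(totalMean[rec] > 0, rm_ / totalMean[rec], 0)
  out <- data.frame(
    sender = grid$sender, receiver = grid$receiver,
    ligand = lig, receptor = rec,
    weight = lm * rm_,
    ligand_detect_frac = ldet, receptor_detect_frac = rdet,
    specificity = spec,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Differences in ligand-receptor edges between two conditions
#'
#' Joins two edge tables on (sender, receiver, ligand, receptor) and reports
#' the weight difference and log-ratio (pseudocount 1e-6); edges present in
#' only one condition are flagged.
#'
#' @param edgesA,edgesB EdgeTables from [extractEdges()] over the same type
#'   and pair universe.
#' @return data.frame with \code{delta = weight_a - weight_b},
#'   \code{log_ratio} and \code{status} (shared / only_a / only_b).
#' @export
diffEdges <- function(edgesA, edgesB) {
  if (!length(intersect(unique(c(edgesA$sender, edgesA$receiver)),
                        unique(c(edgesB$sender, edgesB$receiver)))))
    stop("the two edge tables share no cell types")
  key <- function(e) paste(e$sender, e$receiver, e$ligand, e$receptor,
                           sep = "|")
  ka <- key(edgesA); kb <- key(edgesB)
  allk <- union(ka, kb)
  ia <- match(allk, ka); ib <- match(allk, kb)
  wa <- ifelse(is.na(ia), 0, edgesA$weight[ia])
  wb <- ifelse(is.na(ib), 0, edgesB$weight[ib])
  parts <- do.call(rbind, strsplit(allk, "|", fixed = TRUE))
  eps <- 1e-6
  out <- data.frame(
    sender = parts[, 1], receiver = parts[, 2],
    ligand = parts[, 3], receptor = parts[, 4],
    weight_a = wa, weight_b = wb,
    delta = wa - wb,
    log_ratio = log((wa + eps) / (wb + eps)),
    status = ifelse(is.na(ib), "only_a", ifelse(is.na(ia), "only_b",
                                                "shared")),
    stringsAsFactors = FALSE
  )
  out[order(-abs(out$delta)), ]
}

#' Bundled ligand-receptor pair fixture
#'
#' Reads the editable ligand-receptor pair table shipped with the package
#' (a small curated table including exhaustion-related pairs such as
#' LGALS3-LAG3, CEACAM1-HAVCR2, NECTIN4-TIGIT, HLA-B-KLRD1, MYL9-CD69 and
#' TNFSF10-TNFRSF11B), or any user TSV with \code{ligand} and
#' \code{receptor} columns.
#'
#' @param path optional path to a custom pair TSV.
#' @return data.frame with ligand, receptor, annotation.
#' @export
readLRPairs <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "lr_pairs.tsv", package = "gastroscape")
  read.delim(path, stringsAsFactors = FALSE)
}
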