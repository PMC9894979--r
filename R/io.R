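#' @include AllClasses.R
NULL

#' Write a cohort to a 10x-style directory
#'
#' Serializes a SingleCellExperiment as a Matrix Market triplet
#' (\code{matrix.mtx}, \code{features.tsv}, \code{barcodes.tsv}) plus
#' \code{cells.tsv} (cell metadata), \code{genes.tsv} (BED-like annotation:
#' gene_id, chrom, start, end, is_mitochondrial; 0-based half-open) and, if
#' ground truth is attached, \code{truth.json}.
#'
#' @param sce a SingleCellExperiment with a \code{counts} assay.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(sce, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts <- SummarizedExperiment::assay(sce, "counts")
  Matrix::writeMM(methods::as(counts, "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(sce), file.path(dir, "features.tsv"))
  writeLines(colnames(sce), file.path(dir, "barcodes.tsv"))
  write.table(as.data.frame(SummarizedExperiment::colData(sce)),
              file.path(dir, "cells.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  gdf <- as.data.frame(SummarizedExperiment::rowData(sce))
  names(gdf)[names(gdf) == "start_bp"] <- "start"
  names(gdf)[names(gdf) == "end_bp"] <- "end"
  write.table(gdf, file.path(dir, "genes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  gt <- S4Vectors::metadata(sce)$ground_truth
  if (!is.null(gt)) {
    # named per-cell vectors must become JSON objects, not bare arrays
    for (f in c("lineage", "malignant", "pseudotime_true", "program_of"))
      if (!is.null(gt[[f]])) gt[[f]] <- as.list(gt[[f]])
    jsonlite::write_json(gt, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(dir)
}

#' Read a cohort from a 10x-style directory
#'
#' Inverse of [writeCohort()]; reconstructs the SingleCellExperiment
#' including ground truth when \code{truth.json} is present.
#'
#' @param dir directory written by [writeCohort()].
#' @return a SingleCellExperiment.
#' @export
readCohort <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  rownames(counts) <- readLines(file.path(dir, "features.tsv"))
  colnames(counts) <- readLines(file.path(dir, "barcodes.tsv"))
  cells <- read.delim(file.path(dir, "cells.tsv"), stringsAsFactors = FALSE)
  genes <- read.delim(file.path(dir, "genes.tsv"), stringsAsFactors = FALSE)
  names(genes)[names(genes) == "start"] <- "start_bp"
  names(genes)[names(genes) == "end"] <- "end_bp"
  md <- list()
  tj <- file.path(dir, "truth.json")
  if (file.exists(tj)) {
    gt <- jsonlite::read_json(tj, simplifyVector = TRUE)
    # restore names (and NAs serialized as null) on per-cell vectors
    for (f in c("lineage", "malignant", "pseudotime_true", "program_of"))
      if (!is.null(gt[[f]]) && is.list(gt[[f]])) {
        v <- gt[[f]]
        gt[[f]] <- setNames(
          unlist(lapply(v, function(x) if (is.null(x)) NA else x)),
          names(v))
      }
    md$ground_truth <- gt
  }
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(genes, row.names = genes$gene_id),
    colData = S4Vectors::DataFrame(cells, row.names = cells$cell_id),
    metadata = md
  )
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file: one set per line, tab-separated
#'   (name, description, genes...).
#' @return named list of character vectors.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description description field (recycled).
#' @return \code{path}, invisibly.
#' @export
writeGMT <- function(sets, path, description = "gastroscape") {
  lines <- vapply(names(sets), function(n)
    paste(c(n, description, sets[[n]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Bundled gene-set fixtures
#'
#' Loads the editable curated panels shipped with the package
#' (interferon-alpha/gamma response, exhausted-ligand and
#' costimulatory-ligand panels). These are curation inputs, not computed
#' objects, and users are expected to replace them with their own GMT files
#' for real data.
#'
#' @return named list of character vectors.
#' @export
bundledGeneSets <- function() {
  readGMT(system.file("extdata", "immune_panels.gmt",
                      package = "gastroscape"))
}
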