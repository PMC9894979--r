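#' @include AllClasses.R
NULL

#' Accessors for CnvProfile
#'
#' @param x a [CnvProfile-class] object.
#' @return \code{cnvMatrix}: the cells x windows matrix; \code{cnvWindows}:
#'   the window table; \code{deviationScores}: the named per-cell deviation
#'   vector; \code{cnvBaseline}: the per-window baseline.
#' @name CnvProfile-accessors
NULL

#' @rdname CnvProfile-accessors
#' @export
setGeneric("cnvMatrix", function(x) standardGeneric("cnvMatrix"))
#' @rdname CnvProfile-accessors
#' @export
setMethod("cnvMatrix", "CnvProfile", function(x) x@matrix)

#' @rdname CnvProfile-accessors
#' @export
setGeneric("cnvWindows", function(x) standardGeneric("cnvWindows"))
#' @rdname CnvProfile-accessors
#' @export
setMethod("cnvWindows", "CnvProfile", function(x) x@windows)

#' @rdname CnvProfile-accessors
#' @export
setGeneric("deviationScores", function(x) standardGeneric("deviationScores"))
#' @rdname CnvProfile-accessors
#' @export
setMethod("deviationScores", "CnvProfile", function(x) {
  if (!length(x@deviation))
    stop("deviation not computed yet; run cnvDeviation() first")
  setNames(x@deviation, rownames(x@matrix))
})

#' @rdname CnvProfile-accessors
#' @export
setGeneric("cnvBaseline", function(x) standardGeneric("cnvBaseline"))
#' @rdname CnvProfile-accessors
#' @export
setMethod("cnvBaseline", "CnvProfile", function(x) x@baseline)

setMethod("show", "CnvProfile", function(object) {
  cat("CnvProfile:", nrow(object@matrix), "cells x",
      ncol(object@matrix), "windows over",
      length(unique(object@windows$chrom)), "chromosome(s)\n")
  cat("  baseline subtracted:", object@baselined, "\n")
  if (length(object@deviation))
    cat("  deviation: median", signif(median(object@deviation), 4),
        " range [", signif(min(object@deviation), 4), ", ",
        signif(max(object@deviation), 4), "]\n", sep = "")
})

#' Accessors for GeneSignature
#'
#' @param x a [GeneSignature-class] object.
#' @return \code{signatureGenes}: the final ordered gene vector;
#'   \code{geneProvenance}: the per-candidate flag table.
#' @name GeneSignature-accessors
NULL

#' @rdname GeneSignature-accessors
#' @export
setGeneric("signatureGenes", function(x) standardGeneric("signatureGenes"))
#' @rdname GeneSignature-accessors
#' @export
setMethod("signatureGenes", "GeneSignature", function(x) x@genes)

#' @rdname GeneSignature-accessors
#' @export
setGeneric("geneProvenance", function(x) standardGeneric("geneProvenance"))
#' @rdname GeneSignature-accessors
#' @export
setMethod("geneProvenance", "GeneSignature", function(x) x@provenance)

setMethod("show", "GeneSignature", function(object) {
  cat("GeneSignature '", object@name, "': ", length(object@genes),
      " genes from ", nrow(object@provenance), " candidates\n", sep = "")
  if (length(object@genes))
    cat("  ", paste(head(object@genes, 10), collapse = ", "),
        if (length(object@genes) > 10) ", ..." else "", "\n", sep = "")
})

#' Accessors for ProgramSet
#'
#' @param x a [ProgramSet-class] object.
#' @return \code{programGenes}: named list of program gene lists;
#'   \code{programAssignments}: the factor-to-program table;
#'   \code{factorCorrelations}: the factor-factor Pearson matrix.
#' @name ProgramSet-accessors
NULL

#' @rdname ProgramSet-accessors
#' @export
setGeneric("programGenes", function(x) standardGeneric("programGenes"))
#' @rdname ProgramSet-accessors
#' @export
setMethod("programGenes", "ProgramSet", function(x) x@program_genes)

#' @rdname ProgramSet-accessors
#' @export
setGeneric("programAssignments",
           function(x) standardGeneric("programAssignments"))
#' @rdname ProgramSet-accessors
#' @export
setMethod("programAssignments", "ProgramSet", function(x) x@assignments)

#' @rdname ProgramSet-accessors
#' @export
setGeneric("factorCorrelations",
           function(x) standardGeneric("factorCorrelations"))
#' @rdname ProgramSet-accessors
#' @export
setMethod("factorCorrelations", "ProgramSet", function(x) x@correlation)

setMethod("show", "ProgramSet", function(object) {
  cat("ProgramSet:", nrow(object@assignments), "factors from",
      length(object@factors), "samples;",
      length(object@program_genes), "cross-sample programs\n")
})

#' Accessors for PseudotimePath
#'
#' @param x a [PseudotimePath-class] object.
#' @return \code{pseudotimes}: the named per-cell pseudotime vector;
#'   \code{pathAnchors}: the 3 x n_pcs anchor-centroid matrix.
#' @name PseudotimePath-accessors
NULL

#' @rdname PseudotimePath-accessors
#' @export
setGeneric("pseudotimes", function(x) standardGeneric("pseudotimes"))
#' @rdname PseudotimePath-accessors
#' @export
setMethod("pseudotimes", "PseudotimePath", function(x) x@pseudotime)

#' @rdname PseudotimePath-accessors
#' @export
setGeneric("pathAnchors", function(x) standardGeneric("pathAnchors"))
#' @rdname PseudotimePath-accessors
#' @export
setMethod("pathAnchors", "PseudotimePath", function(x) x@anchors)

setMethod("show", "PseudotimePath", function(object) {
  cat("PseudotimePath:", length(object@pseudotime), "epithelial cells;",
      "anchors at t =", paste(signif(object@waypoints, 3), collapse = ", "),
      "\n")
})
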