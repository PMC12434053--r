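#' @import methods
#' @importFrom stats rnorm rlnorm rnbinom runif prcomp var sd quantile
#'   p.adjust pt wilcox.test cor lm coef residuals setNames aggregate
#' @importFrom utils read.delim write.table read.csv write.csv head
NULL

#' Cell types of the cerebellar reference vocabulary
#'
#' The controlled vocabulary of sorted cerebellar nuclei populations plus
#' the \code{"unsorted"} label used for bulk (mixed) samples.
#'
#' @format Character vector of nine labels.
#' @export
CELL_TYPES <- c("granule", "basket", "golgi", "purkinje",
                "astrocyte", "microglia", "oligodendrocyte", "opc",
                "unsorted")

#' ExpressionMatrix: normalized expression with a scale tag
#'
#' A numeric gene-by-sample matrix carrying a tag identifying its scale:
#' \code{"linear_pm"} (counts per million; columns sum to 1e6) or
#' \code{"log2_pm"} (\code{log2(cpm + pseudocount)}).
#'
#' @slot scaleTag Either \code{"linear_pm"} or \code{"log2_pm"}.
#' @export
setClass("ExpressionMatrix", contains = "matrix",
         representation(scaleTag = "character"))

setValidity("ExpressionMatrix", function(object) {
  if (length(object@scaleTag) != 1L ||
      !object@scaleTag %in% c("linear_pm", "log2_pm"))
    return("scaleTag must be 'linear_pm' or 'log2_pm'")
  if (any(!is.finite(object@.Data)))
    return("expression values must be finite")
  if (object@scaleTag == "log2_pm" && any(object@.Data < 0))
    return("log2_pm values must be >= 0")
  TRUE
})

#' @describeIn ExpressionMatrix scale tag accessor
#' @param x An \code{ExpressionMatrix}.
#' @export
scaleTag <- function(x) {
  stopifnot(is(x, "ExpressionMatrix"))
  x@scaleTag
}

#' Ground-truth reference for synthetic cohorts
#'
#' Per-cell-type mean expression profiles (linear scale, arbitrary units)
#' with a planted marker structure, used by the cohort simulators. Marker
#' lists are disjoint across cell types and every marker gene's mean in its
#' own type is \code{boost} times its mean elsewhere.
#'
#' @slot profiles gene-by-cell-type matrix of linear mean expression.
#' @slot markers named list (one entry per cell type) of marker gene IDs.
#' @slot dispersion per-gene negative-binomial dispersion (inverse size).
#' @slot boost marker enrichment factor.
#' @slot seed seed the reference was drawn with.
#' @export
setClass("GroundTruthReference",
         representation(profiles = "matrix", markers = "list",
                        dispersion = "numeric", boost = "numeric",
                        seed = "integer"))

setValidity("GroundTruthReference", function(object) {
  p <- object@profiles
  if (any(p <= 0)) return("profile means must be > 0")
  if (!all(names(object@markers) %in% colnames(p)))
    return("marker list names must match profile cell types")
  mk <- unlist(object@markers)
  if (anyDuplicated(mk)) return("marker lists must be disjoint across cell types")
  if (!all(mk %in% rownames(p))) return("markers must be profile genes")
  if (any(object@dispersion < 0)) return("dispersion must be >= 0")
  TRUE
})

setMethod("show", "GroundTruthReference", function(object) {
  cat("GroundTruthReference:", nrow(object@profiles), "genes x",
      ncol(object@profiles), "cell types\n")
  cat("  markers/type:", lengths(object@markers)[1],
      " boost:", object@boost,
      " seed:", object@seed, "\n")
})

#' Signature matrix for deconvolution
#'
#' Gene-by-cell-type matrix of mean linear-scale (per-million) reference
#' expression, the basis of both the global and the comparative
#' deconvolution modes.
#'
#' @slot provenance Character note on which samples/profiles were averaged.
#' @export
setClass("SignatureMatrix", contains = "matrix",
         representation(provenance = "character"))

setValidity("SignatureMatrix", function(object) {
  if (any(object@.Data < 0)) return("signature values must be >= 0")
  if (ncol(object@.Data) > 0 && any(colSums(object@.Data) == 0))
    return("signature columns must not be all zero")
  if (is.null(rownames(object@.Data)) || is.null(colnames(object@.Data)))
    return("signature must carry gene rownames and cell-type colnames")
  TRUE
})

setMethod("show", "SignatureMatrix", function(object) {
  cat("SignatureMatrix:", nrow(object), "genes x", ncol(object),
      "cell types (", paste(colnames(object), collapse = ", "), ")\n")
  cat("  provenance:", object@provenance, "\n")
})

#' Comparative deconvolution panel
#'
#' Two-column reference for one target cell type: column 1 is the target
#' signature, column 2 the unweighted average of all other cell types'
#' signatures, restricted to genes on which the pooled rest is homogeneous
#' (see \code{\link{buildComparativePanels}}).
#'
#' @slot target Target cell type.
#' @slot panel Two-column gene-by-signature matrix.
#' @export
setClass("ComparativePanel",
         representation(target = "character", panel = "matrix"))

setValidity("ComparativePanel", function(object) {
  if (ncol(object@panel) != 2L) return("panel must have exactly two columns")
  if (isTRUE(all.equal(object@panel[, 1], object@panel[, 2])))
    return("panel columns must not be identical")
  TRUE
})

setMethod("show", "ComparativePanel", function(object) {
  cat("ComparativePanel for", object@target, "(", nrow(object@panel),
      "genes )\n")
})

#' Specificity-index table
#'
#' Per (gene, cell type) specificity index: the across-iterations average of
#' the gene's mean rank of expression advantage over every other cell type.
#' Low SI means highly specific.
#'
#' @slot si gene-by-cell-type matrix of SI values (>= 1).
#' @slot siSD per (gene, cell type) across-iteration standard deviation of
#'   the mean rank (0 when \code{nIter = 1}).
#' @slot nIter number of bootstrap iterations.
#' @slot seed seed used for the bootstrap.
#' @export
setClass("SpecificityTable",
         representation(si = "matrix", siSD = "matrix", nIter = "integer",
                        seed = "integer"))

setValidity("SpecificityTable", function(object) {
  if (any(object@si < 1)) return("SI values must be >= 1")
  if (!identical(dim(object@si), dim(object@siSD)))
    return("si and siSD must have identical shape")
  TRUE
})

setMethod("show", "SpecificityTable", function(object) {
  cat("SpecificityTable:", nrow(object@si), "genes x", ncol(object@si),
      "cell types;", object@nIter, "iterations\n")
})

#' @describeIn SpecificityTable SI matrix accessor
#' @param x A \code{SpecificityTable}.
#' @export
siValues <- function(x) {
  stopifnot(is(x, "SpecificityTable"))
  x@si
}
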