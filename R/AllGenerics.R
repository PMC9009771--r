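#' Accessors for spqnorm classes
#'
#' `exprValues()`, `scaleTag()` and `meanLogExpr()` access the matrix,
#' scale tag and per-gene mean log-expression of an
#' [ExpressionMatrix-class]; `corValues()` and `covariate()` access the
#' matrix and sort covariate of a [CorrelationMatrix-class];
#' `innerBounds()` and `outerBounds()` return the per-axis interval tables
#' of a [GridPartition-class]; `meanZ()` and `cv2Z()` access the
#' parameters of an [AdjustmentModel-class]. `geneIDs()` works on both
#' matrix classes.
#'
#' @param object an object of the relevant class.
#' @return The slot contents; for `innerBounds()`/`outerBounds()` a
#'   data.frame with columns `start` and `end` (half-open `(start, end]`
#'   intervals of 1-based gene indices).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("exprValues", function(object) standardGeneric("exprValues"))

#' @rdname accessors
#' @export
setGeneric("scaleTag", function(object) standardGeneric("scaleTag"))

#' @rdname accessors
#' @export
setGeneric("meanLogExpr", function(object) standardGeneric("meanLogExpr"))

#' @rdname accessors
#' @export
setGeneric("corValues", function(object) standardGeneric("corValues"))

#' @rdname accessors
#' @export
setGeneric("covariate", function(object) standardGeneric("covariate"))

#' @rdname accessors
#' @export
setGeneric("geneIDs", function(object) standardGeneric("geneIDs"))

#' @rdname accessors
#' @export
setGeneric("innerBounds", function(object) standardGeneric("innerBounds"))

#' @rdname accessors
#' @export
setGeneric("outerBounds", function(object) standardGeneric("outerBounds"))

#' @rdname accessors
#' @export
setGeneric("meanZ", function(object) standardGeneric("meanZ"))

#' @rdname accessors
#' @export
setGeneric("cv2Z", function(object) standardGeneric("cv2Z"))

#' @rdname computeLogRPKM
#' @export
setGeneric("computeLogRPKM", function(object, ...)
    standardGeneric("computeLogRPKM"))

#' @rdname accessors
setMethod("exprValues", "ExpressionMatrix", function(object) object@values)

#' @rdname accessors
setMethod("scaleTag", "ExpressionMatrix", function(object) object@scaleTag)

#' @rdname accessors
setMethod("meanLogExpr", "ExpressionMatrix",
          function(object) object@meanLogExpr)

#' @rdname accessors
setMethod("geneIDs", "ExpressionMatrix",
          function(object) rownames(object@values))

#' @rdname accessors
setMethod("corValues", "CorrelationMatrix", function(object) object@values)

#' @rdname accessors
setMethod("covariate", "CorrelationMatrix", function(object) object@covariate)

#' @rdname accessors
setMethod("geneIDs", "CorrelationMatrix",
          function(object) rownames(object@values))

#' @rdname accessors
setMethod("innerBounds", "GridPartition", function(object)
    data.frame(start = object@innerStart, end = object@innerEnd))

#' @rdname accessors
setMethod("outerBounds", "GridPartition", function(object)
    data.frame(start = object@outerStart, end = object@outerEnd))

#' @rdname accessors
setMethod("meanZ", "AdjustmentModel", function(object) object@meanZ)

#' @rdname accessors
setMethod("cv2Z", "AdjustmentModel", function(object) object@cv2Z)

setMethod("show", "ExpressionMatrix", function(object) {
    cat(sprintf("ExpressionMatrix: %d genes x %d samples [%s]\n",
                nrow(object@values), ncol(object@values), object@scaleTag))
    cat(sprintf("  mean log-expression range: [%.3f, %.3f]\n",
                min(object@meanLogExpr), max(object@meanLogExpr)))
})

setMethod("show", "CorrelationMatrix", function(object) {
    cat(sprintf("CorrelationMatrix: %d genes (sorted by covariate)\n",
                nrow(object@values)))
    off <- object@values[upper.tri(object@values)]
    if (length(off))
        cat(sprintf("  off-diagonal range: [%.3f, %.3f], median %.3f\n",
                    min(off), max(off), stats::median(off)))
    cat(sprintf("  covariate range: [%.3f, %.3f]\n",
                min(object@covariate), max(object@covariate)))
})

setMethod("show", "GridPartition", function(object) {
    cat(sprintf(
        "GridPartition: nGene=%d, nGroup=%d, w=%d, d=%.4g\n",
        object@nGene, object@nGroup, object@w, object@d))
})

setMethod("show", "AdjustmentModel", function(object) {
    cat(sprintf(
        "AdjustmentModel: E(Z)=%.4g, CV2(Z)=%.4g, sd(Z)/sd(Y)=%.5f\n",
        object@meanZ, object@cv2Z, adjustmentFactor(object)))
})

setMethod("dim", "ExpressionMatrix", function(x) dim(x@values))
setMethod("dim", "CorrelationMatrix", function(x) dim(x@values))
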