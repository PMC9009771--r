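#' @import methods
NULL

.SCALE_TAGS <- c("log2rpkm", "log2rpm", "standardized", "residual")

#' ExpressionMatrix: a gene x sample expression matrix with provenance
#'
#' A light container for a real-valued genes x samples matrix together with
#' a tag recording what scale the values are on and the per-gene mean
#' log-expression. The mean log-expression is computed when the object is
#' first put on a log scale and is carried unchanged through
#' standardization and principal-component removal, because it is the
#' covariate along which the correlation matrix is later sorted (rows of a
#' standardized matrix all have mean zero, so the covariate has to be
#' remembered from before standardization).
#'
#' @slot values real matrix, genes as rows; rownames are gene identifiers.
#' @slot scaleTag one of `"log2rpkm"`, `"log2rpm"`, `"standardized"`,
#'   `"residual"`.
#' @slot meanLogExpr named numeric vector, one entry per gene: the average
#'   log-expression across samples on the original log scale.
#'
#' @aliases ExpressionMatrix-class
#' @exportClass ExpressionMatrix
setClass("ExpressionMatrix",
    slots = c(
        values = "matrix",
        scaleTag = "character",
        meanLogExpr = "numeric"
    )
)

setValidity("ExpressionMatrix", function(object) {
    v <- object@values
    msg <- character()
    if (!is.numeric(v))
        msg <- c(msg, "'values' must be a numeric matrix")
    if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
        msg <- c(msg, "'values' must have unique rownames (gene IDs)")
    if (ncol(v) < 2L)
        msg <- c(msg, "at least 2 samples are required")
    if (length(object@scaleTag) != 1L || !object@scaleTag %in% .SCALE_TAGS)
        msg <- c(msg, sprintf("'scaleTag' must be one of: %s",
                              paste(.SCALE_TAGS, collapse = ", ")))
    if (length(object@meanLogExpr) != nrow(v))
        msg <- c(msg, "'meanLogExpr' must have one entry per gene")
    if (identical(object@scaleTag, "standardized") && nrow(v) > 0L) {
        m <- rowMeans(v)
        s2 <- rowSums((v - m)^2) / (ncol(v) - 1L)
        if (max(abs(m)) > 1e-8 || max(abs(s2 - 1)) > 1e-8)
            msg <- c(msg, "standardized rows must have mean 0 and variance 1")
    }
    if (length(msg)) msg else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix (genes x samples) with gene IDs as rownames.
#' @param scaleTag scale of the values; see [ExpressionMatrix-class].
#' @param meanLogExpr per-gene mean log-expression. Defaults to the row
#'   means of `values` when the values are on a log scale; must be supplied
#'   explicitly for standardized or residual values.
#'
#' @return An [ExpressionMatrix-class] object.
#' @export
ExpressionMatrix <- function(values, scaleTag = c("log2rpkm", "log2rpm",
                             "standardized", "residual"),
                             meanLogExpr = NULL) {
    scaleTag <- match.arg(scaleTag)
    if (is.null(meanLogExpr)) {
        if (scaleTag %in% c("standardized", "residual"))
            stop("'meanLogExpr' must be supplied for ", scaleTag, " values")
        meanLogExpr <- rowMeans(values)
    }
    names(meanLogExpr) <- rownames(values)
    new("ExpressionMatrix", values = values, scaleTag = scaleTag,
        meanLogExpr = meanLogExpr)
}

#' CorrelationMatrix: an expression-sorted gene-gene correlation matrix
#'
#' A symmetric Pearson correlation matrix whose rows/columns are sorted by
#' a per-gene covariate (here: mean log-expression, ascending). The sorting
#' is what gives "spatial" meaning to submatrices of the correlation
#' matrix: nearby rows correspond to genes of similar expression level.
#'
#' @slot values symmetric numeric matrix in \[-1, 1\] with unit diagonal;
#'   rownames/colnames are gene identifiers.
#' @slot covariate named numeric vector, non-decreasing along the row
#'   index (the sort covariate, typically mean log2-RPKM).
#'
#' @aliases CorrelationMatrix-class
#' @exportClass CorrelationMatrix
setClass("CorrelationMatrix",
    slots = c(
        values = "matrix",
        covariate = "numeric"
    )
)

setValidity("CorrelationMatrix", function(object) {
    v <- object@values
    msg <- character()
    if (nrow(v) != ncol(v))
        msg <- c(msg, "'values' must be square")
    if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
        msg <- c(msg, "'values' must have identical rownames and colnames")
    if (length(object@covariate) != nrow(v))
        msg <- c(msg, "'covariate' must have one entry per gene")
    if (is.unsorted(object@covariate))
        msg <- c(msg, "'covariate' must be non-decreasing (sorted matrix)")
    if (nrow(v) > 0L) {
        if (!identical(v, t(v)))
            msg <- c(msg, "'values' must be exactly symmetric")
        if (any(diag(v) != 1))
            msg <- c(msg, "diagonal must be exactly 1")
        if (min(v) < -1 || max(v) > 1)
            msg <- c(msg, "entries must lie in [-1, 1]")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a CorrelationMatrix from a precomputed correlation matrix
#'
#' Reorders genes by the covariate (ascending, stable; ties broken by gene
#' ID), forces exact symmetry by averaging with the transpose, clamps
#' rounding excursions outside \[-1, 1\], and sets the diagonal to exactly 1.
#'
#' @param values square symmetric numeric matrix with gene IDs as
#'   row/column names.
#' @param covariate per-gene numeric sort covariate (mean log-expression),
#'   named or in row order of `values`.
#'
#' @return A [CorrelationMatrix-class] object.
#' @export
CorrelationMatrix <- function(values, covariate) {
    if (is.null(rownames(values)))
        stop("'values' must have rownames (gene IDs)")
    if (!is.null(names(covariate))) {
        if (!setequal(names(covariate), rownames(values)))
            stop("names of 'covariate' must match rownames of 'values'")
        covariate <- covariate[rownames(values)]
    }
    if (length(covariate) != nrow(values))
        stop("'covariate' must have one entry per gene")
    if (any(!is.finite(covariate)))
        stop("'covariate' must be finite for every gene")
    ord <- order(covariate, rownames(values), method = "radix")
    values <- values[ord, ord, drop = FALSE]
    covariate <- covariate[ord]
    values <- (values + t(values)) / 2
    values[values > 1] <- 1
    values[values < -1] <- -1
    diag(values) <- 1
    names(covariate) <- rownames(values)
    new("CorrelationMatrix", values = values, covariate = covariate)
}

#' GridPartition: inner bins and outer enclosures over the sorted gene axis
#'
#' Encodes, per axis, the `nGroup` disjoint inner intervals (which tile
#' `1..nGene` exactly) and the `nGroup` overlapping outer enclosures of
#' fixed width `w` used to estimate the local correlation distribution of
#' each inner bin. Intervals are half-open `(start, end]` on 1-based gene
#' indices. The enclosure spacing is `d = (nGene - w) / (nGroup - 1)`,
#' kept as an exact real; integer boundaries are realized by half-up
#' rounding of the real-valued cut points.
#'
#' @slot nGene,nGroup,w integers: number of genes, bins per axis, and
#'   enclosure side length (in genes).
#' @slot d numeric: enclosure spacing `(nGene - w) / (nGroup - 1)`.
#' @slot innerStart,innerEnd integer vectors of length `nGroup`.
#' @slot outerStart,outerEnd integer vectors of length `nGroup`.
#'
#' @aliases GridPartition-class
#' @exportClass GridPartition
setClass("GridPartition",
    slots = c(
        nGene = "integer",
        nGroup = "integer",
        w = "integer",
        d = "numeric",
        innerStart = "integer",
        innerEnd = "integer",
        outerStart = "integer",
        outerEnd = "integer"
    )
)

setValidity("GridPartition", function(object) {
    ng <- object@nGroup
    msg <- character()
    if (length(object@innerStart) != ng || length(object@innerEnd) != ng ||
        length(object@outerStart) != ng || length(object@outerEnd) != ng)
        return("boundary vectors must have length nGroup")
    if (object@innerStart[1L] != 0L || object@innerEnd[ng] != object@nGene)
        msg <- c(msg, "inner bins must cover 1..nGene")
    if (ng > 1L && !identical(object@innerStart[-1L], object@innerEnd[-ng]))
        msg <- c(msg, "inner bins must be contiguous and disjoint")
    if (any(object@innerEnd < object@innerStart))
        msg <- c(msg, "inner bins must have non-negative width")
    if (any(object@outerEnd - object@outerStart != object@w))
        msg <- c(msg, "outer enclosures must have width exactly w")
    if (any(object@innerStart < object@outerStart) ||
        any(object@innerEnd > object@outerEnd))
        msg <- c(msg, "each inner bin must lie inside its outer enclosure")
    if (any(object@outerStart < 0L) || any(object@outerEnd > object@nGene))
        msg <- c(msg, "outer enclosures must lie inside 1..nGene")
    if (length(msg)) msg else TRUE
})

#' AdjustmentModel: Gamma-Poisson parameters of a gene's expression
#'
#' Parameters of the measurement model in which observed counts Y arise
#' from a latent expression level Z through Poisson sampling,
#' `Y | Z ~ Poisson(Z)`. The latent level is described by its mean `E(Z)`
#' (linear scale) and squared coefficient of variation `CV^2(Z)`. These two
#' numbers determine the attenuation `sd(Z)/sd(Y)` that Poisson counting
#' noise applies to correlations involving the gene.
#'
#' @slot meanZ positive numeric, `E(Z)`.
#' @slot cv2Z non-negative numeric, `CV^2(Z) = Var(Z)/E(Z)^2`.
#'
#' @aliases AdjustmentModel-class
#' @exportClass AdjustmentModel
setClass("AdjustmentModel",
    slots = c(meanZ = "numeric", cv2Z = "numeric")
)

setValidity("AdjustmentModel", function(object) {
    msg <- character()
    if (length(object@meanZ) != 1L || !is.finite(object@meanZ) ||
        object@meanZ <= 0)
        msg <- c(msg, "'meanZ' must be a single positive number")
    if (length(object@cv2Z) != 1L || is.na(object@cv2Z) || object@cv2Z < 0)
        msg <- c(msg, "'cv2Z' must be a single non-negative number")
    if (length(msg)) msg else TRUE
})

#' Construct an AdjustmentModel
#'
#' @param meanZ mean latent expression `E(Z)`, linear scale, positive.
#' @param cv2Z squared coefficient of variation `CV^2(Z)`, non-negative.
#' @return An [AdjustmentModel-class] object.
#' @export
AdjustmentModel <- function(meanZ, cv2Z) {
    new("AdjustmentModel", meanZ = as.numeric(meanZ), cv2Z = as.numeric(cv2Z))
}
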