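#' Transform read counts to log2-RPKM (or log2-RPM)
#'
#' Converts a genes x samples count matrix to the log2 reads-per-kilobase
#' per-million scale,
#' `log2((counts + pseudocount) * 1e9 / (libsize * length))`,
#' where the library size of a sample is its total number of reads (the
#' column sum). With `geneLength = NULL` gene length is dropped from the
#' formula and values are log2-RPM
#' (`log2((counts + pseudocount) * 1e6 / libsize)`), the convention used
#' for datasets where no length correction is wanted.
#'
#' For full-length single-cell protocols the pseudocount is conventionally
#' applied after forming RPKM rather than to the raw counts
#' (`log2(RPKM + pseudocount)`); set `pseudocountAfter = TRUE` for that
#' variant.
#'
#' @param object a non-negative integer count matrix (genes x samples,
#'   rownames = gene IDs), or a
#'   [SummarizedExperiment::SummarizedExperiment-class] with a `"counts"`
#'   assay and a `length_bp` column in `rowData`.
#' @param geneLength named numeric vector of gene lengths in bp (one per
#'   gene of `object`), or `NULL` for RPM. Ignored for the
#'   SummarizedExperiment method, which takes lengths from `rowData`.
#' @param pseudocount offset added before taking log2; default 0.5.
#' @param pseudocountAfter apply the pseudocount to RPKM instead of counts.
#' @param ... passed between methods.
#'
#' @return An [ExpressionMatrix-class] with `scaleTag` `"log2rpkm"` (or
#'   `"log2rpm"`), whose `meanLogExpr` records per-gene average
#'   log-expression.
#'
#' @examples
#' counts <- matrix(rpois(20, 50), 4, 5,
#'                  dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
#' len <- setNames(rep(1000, 4), rownames(counts))
#' computeLogRPKM(counts, len)
#' @rdname computeLogRPKM
#' @export
setMethod("computeLogRPKM", "matrix",
    function(object, geneLength = NULL, pseudocount = 0.5,
             pseudocountAfter = FALSE) {
    counts <- object
    if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
        stop("count matrix must have unique rownames (gene IDs)")
    if (any(counts < 0))
        stop("counts must be non-negative")
    libsize <- colSums(counts)
    if (any(libsize <= 0))
        stop("zero library size in sample(s): ",
             paste(colnames(counts)[libsize <= 0], collapse = ", "))
    if (!is.null(geneLength)) {
        if (!is.null(names(geneLength))) {
            missing <- setdiff(rownames(counts), names(geneLength))
            if (length(missing))
                stop("missing annotation for gene(s): ",
                     paste(missing, collapse = ", "))
            geneLength <- geneLength[rownames(counts)]
        } else if (length(geneLength) != nrow(counts)) {
            stop("'geneLength' must have one entry per gene")
        }
        if (any(!is.finite(geneLength) | geneLength < 1))
            stop("gene lengths must be >= 1 bp; offending gene(s): ",
                 paste(rownames(counts)[!is.finite(geneLength) |
                                        geneLength < 1], collapse = ", "))
        denom <- outer(geneLength, libsize) / 1e9
        tag <- "log2rpkm"
    } else {
        denom <- matrix(rep(libsize, each = nrow(counts)) / 1e6,
                        nrow = nrow(counts))
        tag <- "log2rpm"
    }
    if (pseudocountAfter) {
        vals <- log2(counts / denom + pseudocount)
    } else {
        vals <- log2((counts + pseudocount) / denom)
    }
    dimnames(vals) <- dimnames(counts)
    ExpressionMatrix(vals, scaleTag = tag)
})

#' @rdname computeLogRPKM
#' @export
setMethod("computeLogRPKM", "SummarizedExperiment",
    function(object, pseudocount = 0.5, pseudocountAfter = FALSE) {
    counts <- SummarizedExperiment::assay(object, "counts")
    rd <- SummarizedExperiment::rowData(object)
    if (!"length_bp" %in% colnames(rd))
        stop("rowData must contain a 'length_bp' column")
    len <- stats::setNames(as.numeric(rd$length_bp), rownames(object))
    computeLogRPKM(as.matrix(counts), geneLength = len,
                   pseudocount = pseudocount,
                   pseudocountAfter = pseudocountAfter)
})

#' Keep genes whose median log-expression exceeds a threshold
#'
#' Standard expression filter for co-expression analysis: genes whose
#' median log2-RPKM across samples is strictly greater than `threshold`
#' (default 0, i.e. a median above 1 RPKM) are retained, in their original
#' order. For an even number of samples the median is the midpoint of the
#' two central order statistics.
#'
#' @param expr an [ExpressionMatrix-class] on a log scale.
#' @param threshold numeric; default 0.
#' @return The filtered [ExpressionMatrix-class].
#' @export
filterByMedian <- function(expr, threshold = 0) {
    stopifnot(is(expr, "ExpressionMatrix"))
    if (!scaleTag(expr) %in% c("log2rpkm", "log2rpm"))
        stop("'expr' must be on a log scale (log2rpkm or log2rpm)")
    med <- apply(exprValues(expr), 1L, stats::median)
    keep <- med > threshold
    if (!any(keep))
        stop("no genes pass filter")
    ExpressionMatrix(exprValues(expr)[keep, , drop = FALSE],
                     scaleTag = scaleTag(expr),
                     meanLogExpr = meanLogExpr(expr)[keep])
}

#' Standardize each gene to mean 0, variance 1
#'
#' Centers and scales every gene row using the unbiased (n - 1) variance.
#' The per-gene mean log-expression recorded in the input is carried along
#' unchanged, since it is the covariate used later to sort the correlation
#' matrix.
#'
#' @param expr an [ExpressionMatrix-class]; every gene must have nonzero
#'   variance across samples.
#' @return An [ExpressionMatrix-class] with `scaleTag = "standardized"`.
#' @export
standardizeGenes <- function(expr) {
    stopifnot(is(expr, "ExpressionMatrix"))
    v <- exprValues(expr)
    m <- rowMeans(v)
    centered <- v - m
    s <- sqrt(rowSums(centered^2) / (ncol(v) - 1L))
    bad <- s == 0 | !is.finite(s)
    if (any(bad))
        stop("zero-variance gene(s): ",
             paste(rownames(v)[bad], collapse = ", "))
    ExpressionMatrix(centered / s, scaleTag = "standardized",
                     meanLogExpr = meanLogExpr(expr))
}

#' Remove the top principal components from a standardized matrix
#'
#' Computes the top `k` right singular vectors of the standardized
#' genes x samples matrix (principal directions in sample space) and
#' returns, for every gene, the residual of least-squares regression of
#' that gene's row on those `k` component vectors. This is the usual way
#' of removing unwanted variation (batch effects, hidden confounders)
#' before computing gene-gene correlations. Residual rows are orthogonal
#' to each removed component.
#'
#' @param expr a standardized [ExpressionMatrix-class].
#' @param k non-negative integer, number of components to remove;
#'   `k = 0` returns the input with `scaleTag = "residual"`. Must satisfy
#'   `k < min(n_genes, n_samples)`.
#' @return An [ExpressionMatrix-class] with `scaleTag = "residual"`.
#' @export
removeTopPCs <- function(expr, k) {
    stopifnot(is(expr, "ExpressionMatrix"))
    if (!scaleTag(expr) %in% c("standardized"))
        stop("'expr' must be standardized before removing components")
    v <- exprValues(expr)
    k <- as.integer(k)
    if (k < 0L || k >= min(dim(v)))
        stop("'k' must satisfy 0 <= k < min(n_genes, n_samples)")
    if (k > 0L) {
        sv <- svd(v, nu = 0L, nv = k)
        V <- sv$v[, seq_len(k), drop = FALSE]  # orthonormal, sample space
        v <- v - (v %*% V) %*% t(V)
    }
    ExpressionMatrix(v, scaleTag = "residual",
                     meanLogExpr = meanLogExpr(expr))
}

#' Pearson correlation matrix of gene residuals, sorted by expression
#'
#' Computes the gene-gene Pearson correlation matrix of the rows of `expr`
#' and reorders genes by the sort covariate, ascending (stable; ties are
#' broken by gene ID so the ordering is reproducible). By default the
#' covariate is the mean log-expression recorded in the
#' [ExpressionMatrix-class] before standardization/residualization.
#'
#' @param expr an [ExpressionMatrix-class] with at least 3 samples.
#' @param sortCovariate optional per-gene numeric vector overriding the
#'   recorded mean log-expression.
#' @return A [CorrelationMatrix-class].
#' @export
geneCorrelation <- function(expr, sortCovariate = NULL) {
    stopifnot(is(expr, "ExpressionMatrix"))
    v <- exprValues(expr)
    if (ncol(v) < 3L)
        stop("at least 3 samples are required")
    s <- apply(v, 1L, stats::sd)
    if (any(s == 0 | !is.finite(s)))
        stop("zero-variance gene(s): ",
             paste(rownames(v)[s == 0 | !is.finite(s)], collapse = ", "))
    if (is.null(sortCovariate))
        sortCovariate <- meanLogExpr(expr)
    cc <- stats::cor(t(v))
    CorrelationMatrix(cc, covariate = sortCovariate)
}
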