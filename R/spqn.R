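# Equal-size binning of 1..n into nBins contiguous bins; the remainder
# goes to the last bin. Returns integer end points; bin b covers
# (ends[b-1], ends[b]].
equalBinEnds <- function(n, nBins) {
    size <- n %/% nBins
    if (size < 1L)
        stop("fewer genes than bins")
    ends <- as.integer(seq_len(nBins) * size)
    ends[nBins] <- as.integer(n)
    ends
}

binIndices <- function(n, nBins, b) {
    ends <- equalBinEnds(n, nBins)
    starts <- c(0L, ends[-nBins])
    seq.int(starts[b] + 1L, ends[b])
}

#' Default SpQN target: the (9,9) block of a 10 x 10 partition
#'
#' Partitions the expression-sorted gene axis into 10 equal-size bins
#' (remainder genes assigned to the last bin) and returns the sorted
#' off-diagonal correlations of the (9,9) diagonal-block submatrix — the
#' bin of highly (but not extreme top) expressed genes. At high expression
#' the Poisson attenuation of correlations is close to 1, so this block's
#' distribution is the natural reference for what correlations look like
#' when least distorted; the very top block is avoided because it behaves
#' atypically at the boundary of the matrix.
#'
#' @param corr a [CorrelationMatrix-class] over at least 20 genes.
#' @return Sorted numeric vector: the reference (target) distribution.
#' @export
buildTarget <- function(corr) {
    stopifnot(is(corr, "CorrelationMatrix"))
    n <- nrow(corr)
    if (n < 20L)
        stop("at least 20 genes are required to form the default target")
    idx <- binIndices(n, 10L, 9L)
    if (length(idx) < 2L)
        stop("fewer than 2 genes in bin 9")
    block <- corValues(corr)[idx, idx]
    sort(block[upper.tri(block)])
}

# Off-diagonal values of the outer enclosure (i, j): for diagonal blocks
# each unordered pair contributes once (upper triangle); for off-diagonal
# blocks all entries contribute except cells on the global matrix diagonal
# (enclosures of adjacent axes overlap, so such cells can occur).
.enclosureSample <- function(M, rows, cols, diagonalBlock) {
    sub <- M[rows, cols, drop = FALSE]
    if (diagonalBlock) {
        sub[upper.tri(sub)]
    } else {
        hit <- intersect(rows, cols)
        if (length(hit)) {
            drop <- cbind(match(hit, rows), match(hit, cols))
            sub[-((drop[, 2L] - 1L) * length(rows) + drop[, 1L])]
        } else {
            as.vector(sub)
        }
    }
}

#' Spatial quantile normalization of a correlation matrix
#'
#' Normalizes the "local" distribution of correlations across an
#' expression-sorted correlation matrix. The matrix is partitioned (per
#' axis) into `nGroup` disjoint inner bins; the empirical distribution of
#' each inner bin `(i, j)` is estimated from a larger outer enclosure of
#' side `w` centred on the same region (see [makeGrid()]). Every
#' off-diagonal entry `v` of inner bin `(i, j)` is replaced by
#' `q_target(F_emp(v))`, where `F_emp` is the enclosure's empirical CDF
#' ([empiricalCDF()]) and `q_target` the quantile function of the common
#' target distribution ([empiricalQuantile()]). Because adjacent inner
#' bins share most of their enclosures, the fitted maps vary smoothly
#' across bin boundaries; because inner bins are disjoint, every entry is
#' mapped exactly once.
#'
#' Self-correlations are excluded from every empirical distribution and
#' from mapping; the output diagonal is 1. The mapping is applied to the
#' upper triangle and mirrored, so symmetry is preserved bit-exactly, and
#' within each inner bin it is non-decreasing (rank-preserving up to
#' ties). Output entries lie inside the range of the target, hence in
#' `[-1, 1]`.
#'
#' @param corr a [CorrelationMatrix-class] (sorted by covariate,
#'   ascending; the constructor enforces this).
#' @param nGroup number of inner bins per axis; default 60.
#' @param w outer enclosure side length in genes; default 400. Must
#'   satisfy `w <= nGene` and `w * nGroup >= nGene`.
#' @param target optional explicit target distribution (numeric vector of
#'   at least 2 values in `[-1, 1]`). By default the target is taken from
#'   the input matrix itself as the (9,9) block of a 10 x 10 partition
#'   ([buildTarget()]), regardless of `nGroup`.
#' @return A [CorrelationMatrix-class] of the same genes and covariate.
#'
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(60 * 30), 60, 30,
#'             dimnames = list(sprintf("g%02d", 1:60), NULL))
#' expr <- standardizeGenes(ExpressionMatrix(x, "log2rpkm"))
#' corr <- geneCorrelation(expr)
#' norm <- spqnNormalize(corr, nGroup = 3, w = 30)
#' @export
spqnNormalize <- function(corr, nGroup = 60L, w = 400L, target = NULL) {
    stopifnot(is(corr, "CorrelationMatrix"))
    if (is.unsorted(covariate(corr)))
        stop("matrix must be sorted by covariate")
    M <- corValues(corr)
    n <- nrow(M)
    grid <- makeGrid(n, nGroup, w)
    if (is.null(target)) {
        target <- buildTarget(corr)
    } else {
        if (length(target) < 2L || any(!is.finite(target)))
            stop("'target' must contain at least 2 finite values")
        if (min(target) < -1 || max(target) > 1)
            stop("target support must be contained in [-1, 1]")
        target <- sort(target)
    }
    iS <- grid@innerStart; iE <- grid@innerEnd
    oS <- grid@outerStart; oE <- grid@outerEnd
    out <- M
    for (i in seq_len(nGroup)) {
        if (iE[i] == iS[i]) next
        rowsIn <- seq.int(iS[i] + 1L, iE[i])
        rowsOut <- seq.int(oS[i] + 1L, oE[i])
        for (j in i:nGroup) {
            if (iE[j] == iS[j]) next
            colsIn <- seq.int(iS[j] + 1L, iE[j])
            colsOut <- seq.int(oS[j] + 1L, oE[j])
            ref <- .enclosureSample(M, rowsOut, colsOut, i == j)
            if (length(ref) < 2L)
                stop("outer enclosure (", i, ",", j,
                     ") has fewer than 2 off-diagonal values")
            ref <- sort(ref)
            if (i == j) {
                B <- M[rowsIn, colsIn, drop = FALSE]
                ut <- upper.tri(B)
                if (any(ut)) {
                    p <- empiricalCDF(ref, B[ut], sorted = TRUE)
                    B[ut] <- empiricalQuantile(target, p, sorted = TRUE)
                }
                lt <- lower.tri(B)
                B[lt] <- t(B)[lt]
                diag(B) <- 1
                out[rowsIn, colsIn] <- B
            } else {
                B <- M[rowsIn, colsIn, drop = FALSE]
                p <- empiricalCDF(ref, B, sorted = TRUE)
                B[] <- empiricalQuantile(target, p, sorted = TRUE)
                out[rowsIn, colsIn] <- B
                out[colsIn, rowsIn] <- t(B)
            }
        }
    }
    new("CorrelationMatrix", values = out, covariate = covariate(corr))
}
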