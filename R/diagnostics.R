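# Off-diagonal values of submatrix (i, j) under an equal-size nBins
# partition; for i == j the upper triangle (each unordered pair once).
.gridCell <- function(M, n, nBins, i, j) {
    ri <- binIndices(n, nBins, i)
    rj <- binIndices(n, nBins, j)
    sub <- M[ri, rj, drop = FALSE]
    if (i == j) sub[upper.tri(sub)] else as.vector(sub)
}

#' 2D boxplot of the correlation matrix: per-submatrix IQRs
#'
#' Partitions genes into `nBins` equal-size expression bins (remainder to
#' the last bin) and computes, for every `(i, j)` submatrix of the sorted
#' correlation matrix, the interquartile range of its off-diagonal
#' entries (linear-interpolation quantiles). The result is the "2D
#' boxplot" that visualizes the mean-correlation relationship: before
#' normalization the IQR grows with the expression level of the bins, and
#' is approximately a function of the smaller of the two.
#'
#' @param corr a [CorrelationMatrix-class].
#' @param nBins number of expression bins per axis; default 10.
#' @return A list with components `iqr` (`nBins x nBins` symmetric
#'   matrix), `binMeanExpr` (per-bin average covariate) and `minBinExpr`
#'   (`nBins x nBins` matrix, `min(binMeanExpr[i], binMeanExpr[j])`).
#' @export
iqrGrid <- function(corr, nBins = 10L) {
    stopifnot(is(corr, "CorrelationMatrix"))
    M <- corValues(corr)
    n <- nrow(M)
    nBins <- as.integer(nBins)
    ends <- equalBinEnds(n, nBins)
    if (min(diff(c(0L, ends))) < 2L)
        stop("every bin must contain at least 2 genes")
    binMeanExpr <- vapply(seq_len(nBins), function(b)
        mean(covariate(corr)[binIndices(n, nBins, b)]), numeric(1))
    iqr <- matrix(0, nBins, nBins)
    for (i in seq_len(nBins)) {
        for (j in i:nBins) {
            vals <- .gridCell(M, n, nBins, i, j)
            q <- stats::quantile(vals, c(0.25, 0.75), names = FALSE,
                                 type = 7L)
            iqr[i, j] <- iqr[j, i] <- q[2L] - q[1L]
        }
    }
    minBinExpr <- outer(binMeanExpr, binMeanExpr, pmin)
    list(iqr = iqr, binMeanExpr = binMeanExpr, minBinExpr = minBinExpr)
}

#' Split each diagonal expression bin into background and signal
#'
#' For each of `nBins` equal-size expression bins, takes all off-diagonal
#' correlations of gene pairs inside the bin (each unordered pair once) as
#' the background distribution, and the top `signalQ` fraction of those as
#' candidate signal. Selection is by signed value by default (the largest
#' correlations); set `absolute = TRUE` to select by magnitude. The number
#' of signal values is `ceiling(signalQ * n_background)`.
#'
#' @param corr a [CorrelationMatrix-class].
#' @param nBins number of expression bins; default 10.
#' @param signalQ top fraction treated as possible signal, in `(0, 1]`;
#'   default 0.001.
#' @param absolute select signal by `|correlation|` instead of value.
#' @return A list of length `nBins`; each element has components
#'   `background` and `signal` (numeric vectors) and `binMeanExpr`.
#' @export
backgroundSignalSplit <- function(corr, nBins = 10L, signalQ = 0.001,
                                  absolute = FALSE) {
    stopifnot(is(corr, "CorrelationMatrix"))
    if (!is.numeric(signalQ) || signalQ <= 0 || signalQ > 1)
        stop("'signalQ' must lie in (0, 1]")
    M <- corValues(corr)
    n <- nrow(M)
    nBins <- as.integer(nBins)
    lapply(seq_len(nBins), function(b) {
        idx <- binIndices(n, nBins, b)
        bg <- .gridCell(M, n, nBins, b, b)
        k <- ceiling(signalQ * length(bg))
        key <- if (absolute) abs(bg) else bg
        sig <- bg[order(key, decreasing = TRUE)[seq_len(k)]]
        list(background = bg, signal = sig,
             binMeanExpr = mean(covariate(corr)[idx]))
    })
}

# Upper-triangle edge table: correlation, |correlation| and pair mean
# covariate, with a deterministic selection order (value descending, ties
# by lexicographic gene-pair ID).
.edgeTable <- function(corr) {
    M <- corValues(corr)
    n <- nrow(M)
    cov <- covariate(corr)
    ut <- upper.tri(M)
    ij <- which(ut, arr.ind = TRUE)
    ids <- rownames(M)
    data.frame(
        i = ij[, 1L], j = ij[, 2L],
        value = M[ut],
        pairExpr = (cov[ij[, 1L]] + cov[ij[, 2L]]) / 2,
        pairID = paste(ids[ij[, 1L]], ids[ij[, 2L]], sep = "|"),
        row.names = NULL
    )
}

.topEdges <- function(edges, q, absolute = TRUE) {
    k <- ceiling(q * nrow(edges))
    if (k == nrow(edges))  # q = 1 selects everything; keep original order
        return(edges)      # so the bias is exactly zero
    key <- if (absolute) abs(edges$value) else edges$value
    ord <- order(-key, edges$pairID, method = "radix")
    edges[ord[seq_len(k)], , drop = FALSE]
}

#' Expression bias of thresholded co-expression networks
#'
#' For each threshold `q`, selects the top `q` fraction of gene pairs by
#' absolute correlation (deterministic tie-break: value descending, then
#' lexicographic pair ID) and compares the mean pair expression — the
#' average of the two genes' covariates — of the selected pairs with that
#' of all pairs. A positive bias means thresholding over-represents
#' highly expressed genes. At `q = 1` the bias is exactly zero by
#' construction.
#'
#' @param corr a [CorrelationMatrix-class].
#' @param thresholds numeric vector of top fractions in `(0, 1]`.
#' @param absolute select by `|correlation|` (default, the convention for
#'   network thresholding) or by signed value.
#' @return A data.frame with one row per threshold and columns
#'   `threshold`, `meanPairExprTop`, `meanPairExprAll`, `bias` and
#'   `nEdges`.
#' @export
expressionBiasCurve <- function(corr, thresholds, absolute = TRUE) {
    stopifnot(is(corr, "CorrelationMatrix"))
    if (any(thresholds <= 0 | thresholds > 1))
        stop("thresholds must lie in (0, 1]")
    edges <- .edgeTable(corr)
    allMean <- mean(edges$pairExpr)
    rows <- lapply(thresholds, function(q) {
        top <- .topEdges(edges, q, absolute = absolute)
        topMean <- mean(top$pairExpr)
        data.frame(threshold = q, meanPairExprTop = topMean,
                   meanPairExprAll = allMean, bias = topMean - allMean,
                   nEdges = nrow(top))
    })
    do.call(rbind, rows)
}

#' Change in gene-set edge representation after normalization
#'
#' For each threshold `q`, counts the top-`q` edges (by absolute
#' correlation) with at least one endpoint in `geneset`, before and after
#' normalization, and reports the percent change
#' `100 (E_after - E_before) / E_before`. This quantifies, e.g., how many
#' more edges involve transcription factors once the mean-correlation
#' relationship is removed. Thresholds at which no qualifying edge exists
#' before normalization are reported as `NA`.
#'
#' @param corrBefore,corrAfter [CorrelationMatrix-class] objects over the
#'   same genes in the same sorted order.
#' @param geneset character vector of gene IDs.
#' @param thresholds numeric vector of top fractions in `(0, 1]`.
#' @return A data.frame with columns `threshold`, `edgesBefore`,
#'   `edgesAfter` and `percentChange`.
#' @export
genesetEdgeChange <- function(corrBefore, corrAfter, geneset, thresholds) {
    stopifnot(is(corrBefore, "CorrelationMatrix"),
              is(corrAfter, "CorrelationMatrix"))
    if (!identical(geneIDs(corrBefore), geneIDs(corrAfter)))
        stop("matrices must cover the same genes in the same order")
    if (any(thresholds <= 0 | thresholds > 1))
        stop("thresholds must lie in (0, 1]")
    inSet <- geneIDs(corrBefore) %in% geneset
    eb <- .edgeTable(corrBefore)
    ea <- .edgeTable(corrAfter)
    hitB <- inSet[eb$i] | inSet[eb$j]
    hitA <- inSet[ea$i] | inSet[ea$j]
    rows <- lapply(thresholds, function(q) {
        k <- ceiling(q * nrow(eb))
        ordB <- order(-abs(eb$value), eb$pairID, method = "radix")
        ordA <- order(-abs(ea$value), ea$pairID, method = "radix")
        nB <- sum(hitB[ordB[seq_len(k)]])
        nA <- sum(hitA[ordA[seq_len(k)]])
        data.frame(threshold = q, edgesBefore = nB, edgesAfter = nA,
                   percentChange = if (nB == 0) NA_real_ else
                       100 * (nA - nB) / nB)
    })
    do.call(rbind, rows)
}

#' Quantile-quantile comparison of two submatrices
#'
#' Under a 10 x 10 equal-size partition of the sorted correlation matrix,
#' extracts the off-diagonal values of two submatrices and evaluates both
#' quantile functions at probabilities `(k - 0.5) / nQuantiles`. If the
#' two local distributions differ only by a scale factor, the points fall
#' on a straight line through the origin with slope equal to that factor.
#'
#' @param corr a [CorrelationMatrix-class].
#' @param binA,binRef length-2 integer vectors `(i, j)` with entries in
#'   `1..10`, identifying the submatrices to compare (y and x axes).
#' @param nQuantiles number of probability points.
#' @return A data.frame with columns `p`, `qRef` and `qA`.
#' @export
qqPoints <- function(corr, binA, binRef, nQuantiles = 100L) {
    stopifnot(is(corr, "CorrelationMatrix"))
    checkBin <- function(b) {
        if (length(b) != 2L || any(b < 1L) || any(b > 10L))
            stop("bins must be (i, j) pairs with entries in 1..10")
    }
    checkBin(binA); checkBin(binRef)
    M <- corValues(corr)
    n <- nrow(M)
    vA <- .gridCell(M, n, 10L, binA[1L], binA[2L])
    vR <- .gridCell(M, n, 10L, binRef[1L], binRef[2L])
    if (length(vA) < 2L || length(vR) < 2L)
        stop("empty bin")
    p <- (seq_len(nQuantiles) - 0.5) / nQuantiles
    data.frame(p = p,
               qRef = empiricalQuantile(vR, p),
               qA = empiricalQuantile(vA, p))
}

#' Background bias and variance as a function of components removed
#'
#' For each value of `k`, removes the top `k` principal components from
#' the standardized expression matrix, recomputes the sorted correlation
#' matrix, and summarizes the 10 (or `nBins`) diagonal background
#' distributions: the average of the per-bin medians (the background
#' bias, nonzero when unwanted variation shifts supposedly-null
#' correlations off zero) and the average of the per-bin variances.
#'
#' @param expr a standardized [ExpressionMatrix-class].
#' @param kValues integer vector of numbers of components to remove.
#' @param nBins number of diagonal expression bins; default 10.
#' @return A data.frame with columns `k`, `meanBinMedian` and
#'   `meanBinVariance`.
#' @export
pcSweepSummary <- function(expr, kValues, nBins = 10L) {
    stopifnot(is(expr, "ExpressionMatrix"))
    rows <- lapply(kValues, function(k) {
        res <- removeTopPCs(expr, k)
        corr <- geneCorrelation(res)
        M <- corValues(corr)
        n <- nrow(M)
        med <- numeric(nBins)
        va <- numeric(nBins)
        for (b in seq_len(nBins)) {
            vals <- .gridCell(M, n, nBins, b, b)
            med[b] <- stats::median(vals)
            va[b] <- stats::var(vals)
        }
        data.frame(k = as.integer(k), meanBinMedian = mean(med),
                   meanBinVariance = mean(va))
    })
    do.call(rbind, rows)
}
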