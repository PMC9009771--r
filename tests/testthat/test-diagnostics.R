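test_that("iqrGrid computes per-submatrix IQRs on the sorted matrix", {
    # constant matrix: every IQR is zero
    M <- matrix(0.2, 20, 20,
                dimnames = list(sprintf("g%02d", 1:20),
                                sprintf("g%02d", 1:20)))
    diag(M) <- 1
    cst <- CorrelationMatrix(M, covariate = 1:20)
    g <- iqrGrid(cst, nBins = 2)
    expect_true(all(g$iqr == 0))
    expect_identical(g$iqr, t(g$iqr))
    expect_equal(g$binMeanExpr, c(mean(1:10), mean(11:20)))
    expect_equal(g$minBinExpr[1, 2], mean(1:10))

    # 4 genes, 2 bins, hand-enumerated entries
    ids <- paste0("g", 1:4)
    M4 <- matrix(0, 4, 4, dimnames = list(ids, ids))
    M4[1, 2] <- 0.1; M4[1, 3] <- 0.2; M4[1, 4] <- 0.6
    M4[2, 3] <- 0.4; M4[2, 4] <- 0.8; M4[3, 4] <- 0.3
    M4 <- M4 + t(M4); diag(M4) <- 1
    corr4 <- CorrelationMatrix(M4, covariate = 1:4)
    g4 <- iqrGrid(corr4, nBins = 2)
    # cell (1,1) has the single value 0.1 -> IQR 0
    expect_equal(g4$iqr[1, 1], 0)
    # cell (1,2) holds {0.2, 0.6, 0.4, 0.8}: quartiles 0.35 and 0.65
    expect_equal(g4$iqr[1, 2],
                 diff(unname(quantile(c(0.2, 0.6, 0.4, 0.8),
                                      c(0.25, 0.75)))))
    expect_error(iqrGrid(corr4, nBins = 3), "at least 2 genes")
})

test_that("iqrGrid recovers the normal IQR on iid cells", {
    set.seed(301)
    sigma <- 0.05
    corr <- noiseCorrelation(200, sd = sigma)
    g <- iqrGrid(corr, nBins = 2)
    # an off-diagonal cell holds 10^4 iid N(0, sigma) draws
    expect_equal(g$iqr[1, 2], 2 * qnorm(0.75) * sigma, tolerance = 0.05)
})

test_that("diagnostics are invariant to relabeling genes within a bin", {
    set.seed(311)
    corr <- noiseCorrelation(60, covariate = rep(c(1, 2), each = 30))
    M <- corValues(corr)
    perm <- c(sample(1:30), sample(31:60))   # permute within each bin
    Mp <- M[perm, perm]
    corrP <- new("CorrelationMatrix", values = Mp,
                 covariate = setNames(rep(c(1, 2), each = 30),
                                      rownames(Mp)))
    expect_equal(iqrGrid(corr, 2)$iqr, iqrGrid(corrP, 2)$iqr)
    a <- backgroundSignalSplit(corr, 2, signalQ = 0.1)
    b <- backgroundSignalSplit(corrP, 2, signalQ = 0.1)
    expect_equal(sort(a[[1]]$background), sort(b[[1]]$background))
    expect_equal(sort(a[[1]]$signal), sort(b[[1]]$signal))
})

test_that("backgroundSignalSplit returns the top fraction per bin", {
    set.seed(321)
    corr <- noiseCorrelation(40)
    # signalQ = 1: signal is the whole background
    s1 <- backgroundSignalSplit(corr, nBins = 2, signalQ = 1)
    expect_equal(sort(s1[[1]]$signal), sort(s1[[1]]$background))

    # constructed bin: 190 known values, top 2 expected at q = 0.02
    ids <- sprintf("g%02d", 1:20)
    vals <- seq(-0.9, 0.9, length.out = 190)
    M <- matrix(0, 20, 20, dimnames = list(ids, ids))
    M[upper.tri(M)] <- sample(vals)
    M <- M + t(M); diag(M) <- 1
    corr2 <- CorrelationMatrix(M, covariate = 1:20)
    s2 <- backgroundSignalSplit(corr2, nBins = 1, signalQ = 0.02)
    expect_length(s2[[1]]$signal, ceiling(0.02 * 190))
    expect_equal(sort(s2[[1]]$signal, decreasing = TRUE),
                 sort(vals, decreasing = TRUE)[1:4])

    # all-equal bin: signal values equal the constant
    cstM <- matrix(0.1, 20, 20, dimnames = list(ids, ids))
    diag(cstM) <- 1
    s3 <- backgroundSignalSplit(CorrelationMatrix(cstM, 1:20),
                                nBins = 1, signalQ = 0.1)
    expect_true(all(s3[[1]]$signal == 0.1))

    expect_error(backgroundSignalSplit(corr, signalQ = 0), "signalQ")
})

test_that("expressionBiasCurve measures pair-expression bias", {
    set.seed(331)
    corr <- noiseCorrelation(50, covariate = rnorm(50))
    # q = 1: all pairs selected, bias exactly zero
    expect_identical(expressionBiasCurve(corr, 1)$bias, 0)

    # correlations independent of covariate: bias within 3 SE of zero
    b <- expressionBiasCurve(corr, 0.01)
    edges <- spqnorm:::.edgeTable(corr)
    se <- sd(edges$pairExpr) / sqrt(b$nEdges)
    expect_lt(abs(b$bias), 3 * se)

    # perfect confounding: correlation equals pair mean covariate
    ids <- sprintf("g%02d", 1:20)
    cov <- seq(0, 1, length.out = 20)
    M <- outer(cov, cov, function(a, b) (a + b) / 2)
    diag(M) <- 1
    dimnames(M) <- list(ids, ids)
    corr2 <- CorrelationMatrix(M, covariate = setNames(cov, ids))
    q <- 0.05
    b2 <- expressionBiasCurve(corr2, q)
    pe <- spqnorm:::.edgeTable(corr2)$pairExpr
    k <- ceiling(q * length(pe))
    brute <- mean(sort(pe, decreasing = TRUE)[1:k]) - mean(pe)
    expect_equal(b2$bias, brute, tolerance = 1e-12)
})

test_that("genesetEdgeChange counts threshold edges touching the set", {
    set.seed(341)
    corr <- noiseCorrelation(30)
    same <- genesetEdgeChange(corr, corr, geneIDs(corr)[1:5],
                              thresholds = c(0.01, 0.1, 1))
    expect_true(all(same$percentChange == 0))
    all <- genesetEdgeChange(corr, noiseCorrelation(30), geneIDs(corr),
                             thresholds = 0.1)
    expect_equal(all$percentChange, 0)

    # 5-gene toy, enumerated by hand
    ids <- paste0("g", 1:5)
    mk <- function(vals) {
        M <- matrix(0, 5, 5, dimnames = list(ids, ids))
        M[upper.tri(M)] <- vals
        M <- M + t(M); diag(M) <- 1
        CorrelationMatrix(M, covariate = 1:5)
    }
    # upper triangle order: (1,2) (1,3) (2,3) (1,4) (2,4) (3,4) ...
    before <- mk(c(0.9, 0.1, 0.2, 0.1, 0.1, 0.8, 0.1, 0.1, 0.1, 0.7))
    after <- mk(c(0.1, 0.9, 0.1, 0.8, 0.1, 0.1, 0.1, 0.1, 0.7, 0.1))
    # top-3 edges before: (1,2) (3,4) (4,5); after: (1,3) (1,4) (3,5)
    res <- genesetEdgeChange(before, after, geneset = c("g1", "g2"),
                             thresholds = 0.3)
    expect_identical(res$edgesBefore, 1L)
    expect_identical(res$edgesAfter, 2L)
    expect_equal(res$percentChange, 100)

    # no qualifying edge before the threshold: undefined, not an error
    res0 <- genesetEdgeChange(before, after, geneset = "g5",
                              thresholds = 0.1)
    expect_identical(res0$edgesBefore, 0L)
    expect_true(is.na(res0$percentChange))
})

test_that("qqPoints compares submatrix quantiles", {
    set.seed(351)
    corr <- noiseCorrelation(40)
    same <- qqPoints(corr, c(3, 3), c(3, 3), nQuantiles = 20)
    expect_equal(same$qA, same$qRef)

    # construct bin (2,2) = 2 * bin (1,1)
    ids <- sprintf("g%02d", 1:40)
    M <- matrix(0, 40, 40, dimnames = list(ids, ids))
    base <- runif(6, -0.3, 0.3)
    M[1:4, 1:4][upper.tri(matrix(0, 4, 4))] <- base
    M[5:8, 5:8][upper.tri(matrix(0, 4, 4))] <- 2 * base
    M <- M + t(M); diag(M) <- 1
    corr2 <- CorrelationMatrix(M, covariate = 1:40)
    qq <- qqPoints(corr2, c(2, 2), c(1, 1), nQuantiles = 15)
    expect_equal(qq$qA, 2 * qq$qRef, tolerance = 1e-12)

    # two hand-listed bins: quantile pairs by direct sort (6 values fill
    # the upper triangle of a diagonal 4x4 cell exactly)
    vA <- c(0.1, -0.2, 0.4, 0, 0.25)
    vR <- c(-0.5, 0.3, 0.2, -0.1, 0.05)
    M2 <- matrix(0, 40, 40, dimnames = list(ids, ids))
    M2[1:4, 1:4][upper.tri(matrix(0, 4, 4))] <- c(vA, 0.5)
    M2[5:8, 5:8][upper.tri(matrix(0, 4, 4))] <- c(vR, 0.6)
    M2 <- M2 + t(M2); diag(M2) <- 1
    corr3 <- CorrelationMatrix(M2, covariate = 1:40)
    qq3 <- qqPoints(corr3, c(1, 1), c(2, 2), nQuantiles = 6)
    expect_equal(qq3$qA, sort(c(vA, 0.5)), tolerance = 1e-12)
    expect_equal(qq3$qRef, sort(c(vR, 0.6)), tolerance = 1e-12)

    expect_error(qqPoints(corr, c(0, 1), c(1, 1)), "1..10")
})

test_that("pcSweepSummary tracks background bias across removed PCs", {
    set.seed(361)
    nG <- 60; nS <- 40
    shared <- rnorm(nS)
    x <- matrix(rnorm(nG * nS, sd = 0.4), nG, nS) +
        outer(rep(1, nG), shared)
    dimnames(x) <- list(sprintf("g%02d", 1:nG), NULL)
    std <- standardizeGenes(ExpressionMatrix(x, "log2rpkm"))
    sweep <- pcSweepSummary(std, kValues = c(0, 1), nBins = 2)
    # with the shared factor present the background median is far from 0;
    # removing one component collapses it
    expect_gt(sweep$meanBinMedian[1], 0.3)
    expect_lt(abs(sweep$meanBinMedian[2]), 0.1)
    expect_true(all(sweep$meanBinVariance >= 0))

    # hand computation on a tiny case with a single k
    set.seed(362)
    y <- matrix(rnorm(4 * 10), 4, 10,
                dimnames = list(paste0("g", 1:4), NULL))
    stdy <- standardizeGenes(ExpressionMatrix(y, "log2rpkm"))
    s <- pcSweepSummary(stdy, kValues = 0, nBins = 2)
    M <- corValues(geneCorrelation(removeTopPCs(stdy, 0)))
    v11 <- M[1, 2]; v22 <- M[3, 4]
    expect_equal(s$meanBinMedian, mean(c(v11, v22)))
})
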