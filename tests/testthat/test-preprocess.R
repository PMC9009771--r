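makeCounts <- function(m) {
    dimnames(m) <- list(sprintf("g%02d", seq_len(nrow(m))),
                        sprintf("s%02d", seq_len(ncol(m))))
    m
}

test_that("computeLogRPKM evaluates the printed formula", {
    # two samples so the object is valid; library sizes are column sums
    counts <- makeCounts(rbind(c(0, 0), c(1e9, 1e9)))
    len <- c(g01 = 1, g02 = 1)
    expr <- computeLogRPKM(counts, len)
    # gene 1: log2(0.5 * 1e9 / (1e9 * 1)) = -1
    expect_equal(unname(exprValues(expr)["g01", 1]), -1)
    expect_identical(scaleTag(expr), "log2rpkm")

    counts2 <- makeCounts(rbind(c(1, 1), c(999999, 999999)))
    expr2 <- computeLogRPKM(counts2, c(g01 = 1000, g02 = 1000))
    expect_equal(unname(exprValues(expr2)["g01", 1]),
                 log2(1.5e9 / (1e6 * 1000)), tolerance = 1e-12)
    expect_equal(unname(exprValues(expr2)["g01", 1]), 0.5849625,
                 tolerance = 1e-6)

    counts3 <- makeCounts(rbind(c(1023, 1023), c(1e9 - 1023, 1e9 - 1023)))
    expr3 <- computeLogRPKM(counts3, c(g01 = 1024, g02 = 1))
    expect_equal(unname(exprValues(expr3)["g01", 1]),
                 log2(1023.5 / 1024), tolerance = 1e-12)
})

test_that("computeLogRPKM is monotone in counts and validates input", {
    counts <- makeCounts(rbind(c(5, 40), c(995, 960)))
    len <- c(g01 = 500, g02 = 500)
    expr <- computeLogRPKM(counts, len)
    expect_lt(exprValues(expr)["g01", 1], exprValues(expr)["g01", 2])

    expect_error(computeLogRPKM(counts, c(g01 = 500)), "g02")
    zero <- makeCounts(rbind(c(0, 5), c(0, 5)))
    expect_error(computeLogRPKM(zero, len), "library size")
})

test_that("RPM variant and post-hoc pseudocount behave as documented", {
    counts <- makeCounts(rbind(c(10, 10), c(999990, 999990)))
    rpm <- computeLogRPKM(counts, geneLength = NULL)
    expect_identical(scaleTag(rpm), "log2rpm")
    expect_equal(unname(exprValues(rpm)["g01", 1]),
                 log2(10.5 * 1e6 / 1e6), tolerance = 1e-12)

    after <- computeLogRPKM(counts, c(g01 = 1000, g02 = 1000),
                            pseudocountAfter = TRUE)
    rpkm <- 10 * 1e9 / (1e6 * 1000)
    expect_equal(unname(exprValues(after)["g01", 1]), log2(rpkm + 0.5),
                 tolerance = 1e-12)
})

test_that("computeLogRPKM on a SummarizedExperiment matches the matrix path", {
    set.seed(11)
    counts <- makeCounts(matrix(rpois(40, 100), 8, 5))
    len <- stats::setNames(sample(500:2000, 8), rownames(counts))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        rowData = S4Vectors::DataFrame(length_bp = len,
                                       row.names = rownames(counts)))
    expect_equal(exprValues(computeLogRPKM(se)),
                 exprValues(computeLogRPKM(counts, len)))
})

test_that("filterByMedian keeps genes with median strictly above threshold", {
    vals <- rbind(c(-1, 0.5, 0.2),   # median 0.2 -> kept
                  c(-3, 0, 1),       # median 0   -> dropped (strict)
                  c(-0.1, -0.1, -0.1))
    dimnames(vals) <- list(c("keep", "boundary", "low"), NULL)
    expr <- ExpressionMatrix(vals, "log2rpkm")
    kept <- filterByMedian(expr)
    expect_identical(geneIDs(kept), "keep")

    # even sample count: median is the midpoint of the central pair
    vals2 <- rbind(c(-1, 1, 2, -2), c(0, 0, 1, 1))
    dimnames(vals2) <- list(c("mid0", "midhalf"), NULL)
    kept2 <- filterByMedian(ExpressionMatrix(vals2, "log2rpkm"))
    expect_identical(geneIDs(kept2), "midhalf")

    expect_error(filterByMedian(ExpressionMatrix(vals, "log2rpkm"),
                                threshold = 10), "no genes pass")
})

test_that("standardizeGenes centers and scales with n-1 variance", {
    vals <- rbind(c(1, 2, 3), c(4, 0, 2))
    dimnames(vals) <- list(c("a", "b"), NULL)
    std <- standardizeGenes(ExpressionMatrix(vals, "log2rpkm"))
    expect_equal(unname(exprValues(std)["a", ]), c(-1, 0, 1))
    expect_identical(scaleTag(std), "standardized")
    # idempotence: re-standardizing changes nothing
    std2 <- standardizeGenes(
        ExpressionMatrix(exprValues(std), "log2rpkm"))
    expect_equal(exprValues(std2), exprValues(std), tolerance = 1e-12)
    # the sort covariate survives standardization
    expect_equal(unname(meanLogExpr(std)), c(2, 2))

    flat <- rbind(c(5, 5, 5), c(1, 2, 3))
    dimnames(flat) <- list(c("flat", "ok"), NULL)
    expect_error(standardizeGenes(ExpressionMatrix(flat, "log2rpkm")),
                 "flat")
})

test_that("removeTopPCs regresses out leading sample-space components", {
    set.seed(21)
    x <- matrix(rnorm(30 * 10), 30, 10,
                dimnames = list(sprintf("g%02d", 1:30), NULL))
    std <- standardizeGenes(ExpressionMatrix(x, "log2rpkm"))

    expect_equal(exprValues(removeTopPCs(std, 0)), exprValues(std))

    # rank-1 input (standardized rows differ only by sign):
    # removing one component leaves nothing
    u <- rnorm(20); v <- rnorm(8)
    r1 <- outer(u, v)
    dimnames(r1) <- list(sprintf("g%02d", 1:20), NULL)
    std1 <- standardizeGenes(ExpressionMatrix(r1, "log2rpkm"))
    expect_lt(max(abs(exprValues(removeTopPCs(std1, 1)))), 1e-8)
    expect_error(removeTopPCs(ExpressionMatrix(r1, "log2rpkm"), 1),
                 "standardized")

    # orthogonality of residual rows to the removed components
    res <- removeTopPCs(std, 2)
    sv <- svd(exprValues(std), nu = 0, nv = 2)
    expect_lt(max(abs(exprValues(res) %*% sv$v)), 1e-8)
    expect_identical(scaleTag(res), "residual")

    expect_error(removeTopPCs(std, 10), "k")
})

test_that("removeTopPCs removes a planted sample-level batch factor", {
    set.seed(31)
    nG <- 80; nS <- 50
    batch <- rnorm(nS)
    x <- matrix(rnorm(nG * nS, sd = 0.3), nG, nS) +
        outer(rep(1, nG), batch)
    dimnames(x) <- list(sprintf("g%02d", seq_len(nG)), NULL)
    std <- standardizeGenes(ExpressionMatrix(x, "log2rpkm"))
    res <- removeTopPCs(std, 1)
    corWithBatch <- abs(cor(t(exprValues(res)), batch))
    expect_lt(max(corWithBatch), 0.05)
})

test_that("geneCorrelation computes Pearson r and sorts by covariate", {
    x <- rbind(a = c(1, 2, 3), b = c(1, 2, 4), c = c(3, 2, 1))
    expr <- ExpressionMatrix(x, "log2rpkm",
                             meanLogExpr = c(a = 3, b = 1, c = 2))
    corr <- geneCorrelation(expr)
    # sorted by covariate ascending: b, c, a
    expect_identical(geneIDs(corr), c("b", "c", "a"))
    M <- corValues(corr)
    expect_equal(M["a", "b"], 3 / sqrt(2 * 14 / 3), tolerance = 1e-12)
    expect_equal(M["a", "b"], 0.98198, tolerance = 1e-5)
    expect_equal(M["a", "c"], -1)           # x vs reversed x
    expect_identical(diag(M), c(b = 1, c = 1, a = 1))

    dup <- rbind(a = c(1, 2, 3), b = c(2, 4, 6))  # identical up to scale
    corr2 <- geneCorrelation(ExpressionMatrix(dup, "log2rpkm",
                                              meanLogExpr = c(a = 1, b = 2)))
    expect_equal(corValues(corr2)["a", "b"], 1)

    # ties in the covariate break by gene ID
    tie <- ExpressionMatrix(x, "log2rpkm",
                            meanLogExpr = c(a = 1, b = 1, c = 1))
    expect_identical(geneIDs(geneCorrelation(tie)), c("a", "b", "c"))

    flat <- rbind(a = c(1, 1, 1), b = c(1, 2, 3))
    expect_error(geneCorrelation(ExpressionMatrix(flat, "log2rpkm")), "a")
})

test_that("correlation matrices are symmetric with unit diagonal, in [-1,1]", {
    set.seed(41)
    for (rep in 1:5) {
        nG <- sample(10:40, 1)
        nS <- sample(5:30, 1)
        corr <- randomDataCorrelation(nG, nS)
        M <- corValues(corr)
        expect_identical(M, t(M))
        expect_true(all(diag(M) == 1))
        expect_true(min(M) >= -1 && max(M) <= 1)
        expect_false(is.unsorted(covariate(corr)))
    }
})

test_that("the preprocessing pipeline is deterministic", {
    set.seed(51)
    counts <- makeCounts(matrix(rpois(200 * 20, 60), 200, 20))
    len <- stats::setNames(sample(500:2000, 200), rownames(counts))
    run <- function() {
        expr <- filterByMedian(computeLogRPKM(counts, len), threshold = -10)
        corValues(geneCorrelation(removeTopPCs(standardizeGenes(expr), 2)))
    }
    expect_identical(run(), run())
})
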