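# The full fixture pipeline (generate -> log2-RPKM -> filter ->
# standardize -> correlate -> SpQN) is needed by several end-to-end
# checks; run it once per session and memoise the result.
.pipelineCache <- new.env(parent = emptyenv())

fixturePipeline <- function(seed = 1L) {
    key <- paste0("seed", seed)
    if (!is.null(.pipelineCache[[key]]))
        return(.pipelineCache[[key]])
    se <- meanCorrelationFixture(seed = seed)
    expr <- filterByMedian(computeLogRPKM(se))
    std <- standardizeGenes(expr)
    corr <- geneCorrelation(std)
    # enclosure bandwidth scaled to the fixture's matrix size: w = 100 on
    # ~2000 genes is the same relative bandwidth as the default w = 400
    # on a bulk-sized (~12000 gene) matrix
    norm <- spqnNormalize(corr, w = 100L)
    res <- list(se = se, expr = expr, corr = corr, norm = norm,
                target = buildTarget(corr))
    .pipelineCache[[key]] <- res
    res
}

# Off-diagonal values of submatrix (i, j) of a plain matrix under an
# equal-size nBins partition (upper triangle for diagonal cells).
cellValues <- function(M, nBins, i, j) {
    n <- nrow(M)
    size <- n %/% nBins
    ends <- seq_len(nBins) * size
    ends[nBins] <- n
    starts <- c(0L, ends[-nBins])
    ri <- (starts[i] + 1L):ends[i]
    rj <- (starts[j] + 1L):ends[j]
    sub <- M[ri, rj, drop = FALSE]
    if (i == j) sub[upper.tri(sub)] else as.vector(sub)
}
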