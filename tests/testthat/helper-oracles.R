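# Independent re-implementations used as oracles. These deliberately do
# not call the package's empiricalCDF/empiricalQuantile internals.

# Classical quantile normalization of a value multiset into a target
# distribution: each value is replaced by the target quantile at its
# midrank plotting position, interpolating linearly between target order
# statistics placed at (k - 0.5)/M.
qnOracle <- function(vals, target) {
    m <- length(vals)
    r <- rank(vals, ties.method = "average")
    p <- (r - 0.5) / m
    ts <- sort(target)
    M <- length(ts)
    vapply(p, function(pp) {
        pos <- pp * M + 0.5
        if (pos <= 1) {
            ts[1L]
        } else if (pos >= M) {
            ts[M]
        } else {
            k <- floor(pos)
            ts[k] + (pos - k) * (ts[k + 1L] - ts[k])
        }
    }, numeric(1))
}

# Midrank CDF and plotting-position quantile by explicit counting loops.
cdfOracle <- function(sample, x) {
    m <- length(sample)
    p <- (sum(sample < x) + 0.5 * sum(sample == x)) / m
    min(max(p, 0.5 / m), 1 - 0.5 / m)
}

quantileOracle <- function(sample, p) {
    ts <- sort(sample)
    M <- length(ts)
    pos <- p * M + 0.5
    if (pos <= 1) return(ts[1L])
    if (pos >= M) return(ts[M])
    k <- floor(pos)
    ts[k] + (pos - k) * (ts[k + 1L] - ts[k])
}

# A CorrelationMatrix filled with iid noise correlations (not a true
# Gram matrix, but symmetric with unit diagonal and entries in [-1, 1] --
# exactly what the normalization and diagnostics operate on).
noiseCorrelation <- function(nGene, sd = 0.1, covariate = NULL) {
    ids <- sprintf("g%04d", seq_len(nGene))
    M <- matrix(0, nGene, nGene, dimnames = list(ids, ids))
    ut <- upper.tri(M)
    M[ut] <- pmin(pmax(rnorm(sum(ut), sd = sd), -1), 1)
    M <- M + t(M)
    diag(M) <- 1
    if (is.null(covariate))
        covariate <- seq_len(nGene)
    CorrelationMatrix(M, covariate = stats::setNames(covariate, ids))
}

# A CorrelationMatrix computed from random expression data.
randomDataCorrelation <- function(nGene, nSample) {
    x <- matrix(rnorm(nGene * nSample), nGene, nSample,
                dimnames = list(sprintf("g%04d", seq_len(nGene)), NULL))
    expr <- standardizeGenes(ExpressionMatrix(x, "log2rpkm"))
    geneCorrelation(expr)
}
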