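#' Empirical CDF with midrank ties, at plotting positions
#'
#' Evaluates the empirical distribution function of a sample using the
#' midrank convention for ties,
#' `F(x) = (#\{values < x\} + 0.5 #\{values = x\}) / m`,
#' clamped to `[0.5/m, 1 - 0.5/m]` so that the result is always a usable
#' quantile probability. With this convention, evaluating the CDF at the
#' k-th distinct order statistic returns the plotting position
#' `(k - 0.5)/m`, so [empiricalQuantile()] of a distribution at its own
#' CDF values reproduces the sample exactly — the round-trip identity the
#' normalization relies on.
#'
#' @param values numeric sample (the empirical distribution), at least 2
#'   finite values.
#' @param x numeric vector of query points.
#' @param sorted set to `TRUE` if `values` is already sorted ascending
#'   (skips the sort).
#' @return Numeric vector of probabilities in `(0, 1)`, same length as `x`.
#'
#' @examples
#' empiricalCDF(c(1, 2, 3, 4), 2)    # (1 + 0.5)/4 = 0.375
#' empiricalCDF(c(1, 2, 3, 4), 0)    # clamped to 0.5/4
#' @export
empiricalCDF <- function(values, x, sorted = FALSE) {
    if (!sorted)
        values <- sort(values)
    m <- length(values)
    if (m < 2L)
        stop("empirical distribution needs at least 2 values")
    nLE <- findInterval(x, values)
    nLT <- findInterval(x, values, left.open = TRUE)
    p <- (nLT + 0.5 * (nLE - nLT)) / m
    pmin(pmax(p, 0.5 / m), 1 - 0.5 / m)
}

#' Empirical quantile by linear interpolation of plotting positions
#'
#' Evaluates the quantile function of a sample by linear interpolation of
#' the order statistics placed at plotting positions `(k - 0.5)/m`.
#' Probabilities below the first plotting position return the sample
#' minimum; above the last, the maximum. This is the inverse of
#' [empiricalCDF()] on distinct values.
#'
#' @param values numeric sample, at least 2 finite values.
#' @param p numeric vector of probabilities in `(0, 1)`.
#' @param sorted set to `TRUE` if `values` is already sorted ascending.
#' @return Numeric vector, same length as `p`.
#'
#' @examples
#' empiricalQuantile(c(1, 2, 3, 4), 0.375)  # 2
#' empiricalQuantile(c(0, 10), 0.5)         # 5
#' @export
empiricalQuantile <- function(values, p, sorted = FALSE) {
    if (any(p <= 0 | p >= 1))
        stop("probabilities must lie strictly inside (0, 1)")
    if (!sorted)
        values <- sort(values)
    m <- length(values)
    if (m < 2L)
        stop("empirical distribution needs at least 2 values")
    pk <- (seq_len(m) - 0.5) / m
    stats::approx(pk, values, xout = p, rule = 2L, ties = "ordered")$y
}
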