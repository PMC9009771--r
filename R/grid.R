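# Half-up rounding (R's round() is round-half-even; the grid boundaries
# need the deterministic "round 0.5 up" convention).
roundHalfUp <- function(x) as.integer(floor(x + 0.5))

#' Build the inner-bin / outer-enclosure partition of the gene axis
#'
#' Constructs, for a correlation matrix over `nGene` expression-sorted
#' genes, the per-axis geometry used by spatial quantile normalization:
#' `nGroup` overlapping outer enclosures of width `w` spaced
#' `d = (nGene - w) / (nGroup - 1)` genes apart, and `nGroup` disjoint
#' inner bins that tile `1..nGene` exactly, each inner bin centered inside
#' its enclosure. Enclosure `x` covers genes in
#' `(round((x-1) d), round((x-1) d) + w]`; the inner boundaries follow the
#' real-valued cut points `d/2 + w/2 + (x-1) d`, rounded half-up, with the
#' last bin ending exactly at `nGene`. `d` is kept as an exact real;
#' because half-up rounding is monotone and `d <= w`, every inner bin is
#' contained in its enclosure.
#'
#' When `d = w` (i.e. `w * nGroup = nGene` with bins exactly abutting)
#' inner bins and enclosures coincide and spatial quantile normalization
#' reduces to classical per-bin quantile normalization.
#'
#' @param nGene number of genes (matrix side length).
#' @param nGroup number of bins per axis, `>= 2`.
#' @param w enclosure side length in genes, `2 <= w <= nGene`.
#' @return A [GridPartition-class].
#'
#' @examples
#' makeGrid(400, 10, 40)   # d = w: inner bins coincide with enclosures
#' makeGrid(12000, 60, 400)
#' @export
makeGrid <- function(nGene, nGroup, w) {
    nGene <- as.integer(nGene)
    nGroup <- as.integer(nGroup)
    w <- as.integer(w)
    if (nGroup < 2L)
        stop("'nGroup' must be at least 2")
    if (w < 2L)
        stop("'w' must be at least 2")
    if (w > nGene)
        stop("enclosure larger than matrix")
    if (as.double(w) * nGroup < nGene)
        stop("bins cannot be contained in enclosures; increase w or nGroup")
    d <- (nGene - w) / (nGroup - 1)
    x <- seq_len(nGroup)
    outerStart <- roundHalfUp((x - 1) * d)
    outerEnd <- outerStart + w
    innerEnd <- roundHalfUp(d / 2 + w / 2 + (x - 1) * d)
    innerEnd[nGroup] <- nGene
    innerStart <- c(0L, innerEnd[-nGroup])
    new("GridPartition", nGene = nGene, nGroup = nGroup, w = w, d = d,
        innerStart = innerStart, innerEnd = innerEnd,
        outerStart = outerStart, outerEnd = outerEnd)
}
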