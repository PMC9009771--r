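#' Poisson attenuation factor sd(Z)/sd(Y)
#'
#' Under the Gamma-Poisson measurement model (`Y | Z ~ Poisson(Z)`), the
#' observed counts Y carry the latent variation of Z plus Poisson counting
#' noise, so `Var(Y) = Var(Z) + E(Z)` and the correlation of two genes is
#' attenuated by each gene's factor
#' `sd(Z)/sd(Y) = sqrt(CV2(Z) / (1/E(Z) + CV2(Z)))`.
#' The factor is 0 when the gene has no true variation, strictly below 1
#' for finite expression, and tends to 1 as `E(Z)` grows — which is why
#' observed correlations are systematically closer to zero for lowly
#' expressed genes.
#'
#' @param model an [AdjustmentModel-class], or the mean `E(Z)` if `cv2Z`
#'   is also given.
#' @param cv2Z optional `CV^2(Z)` when `model` is given as a plain number.
#' @return The attenuation factor in `[0, 1)`.
#'
#' @examples
#' adjustmentFactor(AdjustmentModel(meanZ = 1, cv2Z = 1))  # sqrt(0.5)
#' adjustmentFactor(1e12, 1)                               # ~ 1
#' @export
adjustmentFactor <- function(model, cv2Z = NULL) {
    if (!is(model, "AdjustmentModel")) {
        if (is.null(cv2Z))
            stop("supply an AdjustmentModel or both meanZ and cv2Z")
        model <- AdjustmentModel(model, cv2Z)
    }
    sqrt(model@cv2Z / (1 / model@meanZ + model@cv2Z))
}

#' Observed correlation implied by a latent correlation
#'
#' The Gamma-Poisson model implies
#' `Cor(Y1, Y2) = Cor(Z1, Z2) * sd(Z1)/sd(Y1) * sd(Z2)/sd(Y2)`:
#' the observed correlation is the latent one shrunk by both genes'
#' attenuation factors, so its magnitude never exceeds `|rhoZ|`.
#'
#' @param rhoZ latent correlation in `[-1, 1]`.
#' @param model1,model2 [AdjustmentModel-class] objects for the two genes.
#' @return The implied observed correlation.
#' @export
observedCorrelation <- function(rhoZ, model1, model2) {
    if (abs(rhoZ) > 1)
        stop("'rhoZ' must lie in [-1, 1]")
    rhoZ * adjustmentFactor(model1) * adjustmentFactor(model2)
}

# Gaussian-copula parameter giving gamma-marginal pairs the requested
# Pearson correlation. The copula parameter and the induced correlation
# differ for non-normal marginals, so we calibrate by monotone
# root-finding on the empirical correlation of a fixed calibration
# sample (common random numbers make the objective monotone in r).
# Calibration runs on its own fixed RNG substream -- it neither consumes
# nor depends on the caller's seed -- which also makes it safe to
# memoise.
.copulaCache <- new.env(parent = emptyenv())

calibrateCopula <- function(rhoZ, shape, nCal = 2e5, tol = 0.005) {
    if (rhoZ == 0)
        return(0)
    key <- paste(signif(rhoZ, 12), signif(shape, 12), nCal, tol,
                 sep = "|")
    if (!is.null(.copulaCache[[key]]))
        return(.copulaCache[[key]])
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", globalenv(), inherits = FALSE)
        on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
    } else {
        on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
                add = TRUE)
    }
    set.seed(987654321L)
    A <- stats::rnorm(nCal)
    B <- stats::rnorm(nCal)
    gA <- stats::qgamma(stats::pnorm(A), shape = shape, rate = 1)
    empCor <- function(r) {
        W2 <- r * A + sqrt(1 - r^2) * B
        stats::cor(gA, stats::qgamma(stats::pnorm(W2), shape = shape,
                                     rate = 1))
    }
    s <- sign(rhoZ)
    hi <- 1 - 1e-7
    if (s * empCor(s * hi) < s * rhoZ)
        stop("requested |rhoZ| too close to 1 for gamma marginals")
    root <- stats::uniroot(function(r) empCor(r) - rhoZ,
                           interval = sort(c(0, s * hi)), tol = tol)$root
    .copulaCache[[key]] <- root
    root
}

#' Monte-Carlo verification of the correlation attenuation identity
#'
#' Draws `n` paired latent expression values `(Z1, Z2)` with Gamma
#' marginals (shape `1/cv2Z`, scale `meanZ * cv2Z`) coupled through a
#' Gaussian copula calibrated so the realized Pearson correlation matches
#' `rhoZ`, then draws observed counts `Y | Z ~ Poisson(Z)` independently
#' per gene, and compares both sides of
#' `Cor(Y1, Y2) = Cor(Z1, Z2) * sd(Z1)/sd(Y1) * sd(Z2)/sd(Y2)`
#' using empirical moments of the same sample. Both sides therefore share
#' the sampling noise of the latent draw, and the reported discrepancy
#' isolates the conditional-independence structure of the sequencing
#' noise rather than copula calibration error.
#'
#' @param rhoZ target latent correlation in `(-1, 1)`.
#' @param n number of samples, at least 10.
#' @param meanZ,cv2Z shared Gamma-Poisson parameters of both genes;
#'   `cv2Z` must be positive.
#' @param seed integer seed for the draw.
#' @return A list with components `corY` (empirical observed
#'   correlation), `corZscaled` (empirical latent correlation times both
#'   empirical attenuation factors), `discrepancy` (absolute difference),
#'   plus `corZ`, `varY1`, `varZ1` and `meanZ1` for checking the
#'   variance decomposition `Var(Y) = Var(Z) + E(Z)`.
#' @export
verifyIdentityMC <- function(rhoZ, n, meanZ, cv2Z, seed = 1L) {
    if (abs(rhoZ) >= 1)
        stop("'rhoZ' must lie strictly inside (-1, 1)")
    if (n < 10L)
        stop("'n' must be at least 10")
    if (cv2Z <= 0)
        stop("'cv2Z' must be positive for a Monte-Carlo check")
    if (meanZ <= 0)
        stop("'meanZ' must be positive")
    set.seed(as.integer(seed))
    shape <- 1 / cv2Z
    scale <- meanZ * cv2Z
    r <- calibrateCopula(rhoZ, shape)
    W1 <- stats::rnorm(n)
    W2 <- r * W1 + sqrt(1 - r^2) * stats::rnorm(n)
    Z1 <- stats::qgamma(stats::pnorm(W1), shape = shape, scale = scale)
    Z2 <- stats::qgamma(stats::pnorm(W2), shape = shape, scale = scale)
    Y1 <- stats::rpois(n, Z1)
    Y2 <- stats::rpois(n, Z2)
    corY <- stats::cor(Y1, Y2)
    corZ <- stats::cor(Z1, Z2)
    corZscaled <- corZ * stats::sd(Z1) / stats::sd(Y1) *
        stats::sd(Z2) / stats::sd(Y2)
    list(corY = corY, corZscaled = corZscaled,
         discrepancy = abs(corY - corZscaled), corZ = corZ,
         varY1 = stats::var(Y1), varZ1 = stats::var(Z1),
         meanZ1 = mean(Z1))
}
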