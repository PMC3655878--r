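#' Hardy-Weinberg genotype frequencies
#'
#' Expected frequencies of the AA, AB and BB genotypes at a biallelic locus
#' in Hardy-Weinberg equilibrium, given the frequency of allele A. With
#' \code{alleleFreq = 0.3} these are 0.09, 0.42 and 0.49.
#'
#' @param alleleFreq frequency of allele A, strictly inside (0, 1).
#' @return named numeric vector \code{c(AA =, AB =, BB =)} summing to 1.
#' @examples
#' hweGenotypeProbs(0.3)
#' @export
hweGenotypeProbs <- function(alleleFreq) {
    if (!is.numeric(alleleFreq) || length(alleleFreq) != 1L ||
        !is.finite(alleleFreq) || alleleFreq <= 0 || alleleFreq >= 1)
        stop("'alleleFreq' must be a single value in (0, 1)")
    p <- alleleFreq
    c(AA = p^2, AB = 2 * p * (1 - p), BB = (1 - p)^2)
}

#' Simulate genotypes at a SNP in Hardy-Weinberg equilibrium
#'
#' Each individual's allele-A count is the sum of two independent
#' Bernoulli(\code{alleleFreq}) allele draws, i.e. Binomial(2, alleleFreq),
#' which is exactly the HWE genotype distribution.
#'
#' @param n number of individuals.
#' @param alleleFreq frequency of allele A in (0, 1).
#' @param seed optional seed; if NULL the current RNG stream is used.
#' @return integer vector of length n with values in \{0, 1, 2\}
#'   (copies of allele A; 2 = AA, 1 = AB, 0 = BB).
#' @examples
#' g <- simulateGenotypes(10000, 0.3, seed = 1)
#' mean(g == 1)  # close to 0.42
#' @export
simulateGenotypes <- function(n, alleleFreq, seed = NULL) {
    if (n < 1) stop("'n' must be >= 1")
    hweGenotypeProbs(alleleFreq)  # validates alleleFreq
    if (!is.null(seed)) set.seed(as.integer(seed))
    as.integer(stats::rbinom(n, 2L, alleleFreq))
}

#' Genotype-specific phenotype mean under the multiplicative effect model
#'
#' If BB individuals have mean 1, carrying each additional copy of allele A
#' multiplies the phenotype mean by delta: means are 1, delta and delta^2
#' for BB, AB and AA. delta = 1 gives the null of no genotype effect. The
#' model is the quantitative-trait analogue of a genotypic relative risk
#' model.
#'
#' @param count allele-A count(s), each 0, 1 or 2 (vectorized).
#' @param effectSize delta > 0.
#' @return numeric vector of phenotype means, \code{effectSize^count}.
#' @examples
#' genotypeMean(0:2, 1.2)  # 1, 1.2, 1.44
#' @export
genotypeMean <- function(count, effectSize) {
    if (!is.numeric(effectSize) || effectSize <= 0)
        stop("'effectSize' must be > 0")
    if (any(!count %in% c(0, 1, 2)))
        stop("'count' entries must be 0, 1 or 2")
    effectSize^count
}

#' Equicorrelation matrix
#'
#' The m x m matrix with unit diagonal and constant off-diagonal r. Its
#' eigenvalues are 1 + (m-1) r (once) and 1 - r (m-1 times), so it is
#' positive definite exactly when -1/(m-1) < r < 1.
#'
#' @param m dimension (number of traits).
#' @param r common pairwise correlation.
#' @return m x m numeric matrix.
#' @examples
#' equicorrMatrix(3, 0.5)
#' @export
equicorrMatrix <- function(m, r) {
    m <- as.integer(m)
    if (m < 1L) stop("'m' must be >= 1")
    if (m > 1L && (r <= -1 / (m - 1) || r >= 1))
        stop(sprintf(
            "'r' must lie in (-1/(m-1), 1) = (%.4f, 1) for m = %d",
            -1 / (m - 1), m))
    S <- matrix(r, m, m)
    diag(S) <- 1
    S
}

## Monotone per-cell maps that turn the latent normal draw into a
## non-normal marginal while preserving ranks (hence Spearman correlation
## and the ordering of genotype effects). The chisq map is anchored at the
## null marginal N(1, 1), so under delta = 1 the traits are exactly
## chi-squared with 3 df.
.familyTransform <- function(X, family) {
    switch(family,
        normal    = X,
        lognormal = exp(X),
        chisq     = stats::qchisq(stats::pnorm(X, mean = 1), df = 3),
        stop("unknown family: ", family))
}

#' Simulate correlated phenotypes given genotypes
#'
#' Row i of the result is drawn from an m-variate normal with every
#' coordinate mean equal to \code{genotypeMean(g[i], delta)} (1, delta or
#' delta^2), unit variances and common correlation r, i.e. covariance
#' \code{equicorrMatrix(m, r)}. For \code{family != "normal"} a fixed
#' monotone map is then applied to every cell (exp for "lognormal", a
#' chi-squared(3) quantile transform anchored at the null marginal N(1,1)
#' for "chisq"), which preserves the rank correlation structure and the
#' ordering of the genotype effect.
#'
#' @param g integer vector of allele-A counts (no missing values).
#' @param config a \linkS4class{SimulationConfig}; \code{nSamples} is taken
#'   from \code{length(g)}.
#' @param seed optional seed; if NULL the current RNG stream is used.
#' @return numeric matrix, \code{length(g)} x \code{nPhenotypes(config)},
#'   with column names P1..Pm.
#' @examples
#' cfg <- SimulationConfig(nSamples = 100, nPhenotypes = 3,
#'                         effectSize = 1.2, correlation = 0.5)
#' g <- simulateGenotypes(100, 0.3, seed = 1)
#' Y <- simulatePhenotypes(g, cfg)
#' @export
simulatePhenotypes <- function(g, config, seed = NULL) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    if (anyNA(g)) stop("'g' must not contain missing values")
    n <- length(g)
    m <- config@nPhenotypes
    if (!is.null(seed)) set.seed(as.integer(seed))
    R <- chol(equicorrMatrix(m, config@correlation))
    Y <- matrix(stats::rnorm(n * m), n, m) %*% R
    Y <- Y + genotypeMean(g, config@effectSize)  # recycled down columns
    Y <- .familyTransform(Y, config@family)
    colnames(Y) <- paste0("P", seq_len(m))
    Y
}

#' Simulate one genotype-phenotype replicate
#'
#' Draws genotypes under HWE, then phenotypes under the multiplicative
#' genotype-mean model, using a seed derived deterministically from the
#' config's root seed and the replicate index. Replicate k is therefore
#' reproducible in isolation: the same (seed, replicate) pair always yields
#' the same dataset, independent of any other replicate.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param replicate replicate index k >= 1.
#' @return list with elements \code{genotypes} (integer vector, length n)
#'   and \code{phenotypes} (n x m matrix).
#' @examples
#' d <- simulateDataset(SimulationConfig(nSamples = 50, nPhenotypes = 3))
#' str(d)
#' @export
simulateDataset <- function(config, replicate = 1L) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    set.seed(.spawnSeed(config@seed, replicate))
    g <- simulateGenotypes(config@nSamples, config@alleleFreq)
    Y <- simulatePhenotypes(g, config)
    list(genotypes = g, phenotypes = Y)
}

#' Inject missing values at random
#'
#' Masks each entry independently with the given probability; used to make
#' synthetic fixtures resemble real candidate-SNP tables. Off by default in
#' all simulation paths.
#'
#' @param x vector or matrix.
#' @param rate per-entry missingness probability in [0, 1).
#' @return \code{x} with entries replaced by NA.
#' @export
injectMissing <- function(x, rate) {
    if (rate < 0 || rate >= 1) stop("'rate' must lie in [0, 1)")
    if (rate > 0) x[stats::runif(length(x)) < rate] <- NA
    x
}
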