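#' @include AllGenerics.R
NULL

## Method identifiers shared across the package. "one_by_one" is the
## per-trait + Bonferroni strategy; the other three are as named.
.MPAT_METHODS <- c("one_by_one", "permutation", "manova", "pca")

#' Simulation design for one genotype-phenotype scenario
#'
#' Holds every generative parameter of the simulation model: a biallelic SNP
#' in Hardy-Weinberg equilibrium with allele-A frequency \code{alleleFreq},
#' and an n x m matrix of quantitative traits drawn from an equicorrelated
#' multivariate normal whose common mean is \code{effectSize^g} for an
#' individual carrying \code{g} copies of allele A (so means are 1, delta,
#' delta^2 for BB, AB, AA; delta = 1 is the null of no association).
#'
#' @slot alleleFreq frequency of allele A, in (0, 1).
#' @slot nSamples number of individuals n.
#' @slot nPhenotypes number of traits m.
#' @slot effectSize multiplicative per-allele effect delta (> 0); 1 = null.
#' @slot correlation common pairwise trait correlation r; must satisfy
#'   r > -1/(m-1) and r < 1 so the equicorrelation matrix is positive
#'   definite.
#' @slot family marginal trait distribution: "normal", or the monotone
#'   transformed families "lognormal" / "chisq".
#' @slot nReplicates number of Monte-Carlo replicates a power run uses.
#' @slot seed root random seed; replicate k derives its own stream from it.
#'
#' @examples
#' cfg <- SimulationConfig(nSamples = 300, nPhenotypes = 10,
#'                         effectSize = 1.2, correlation = 0.5)
#' cfg
#' @export SimulationConfig
#' @exportClass SimulationConfig
setClass("SimulationConfig",
    representation(
        alleleFreq   = "numeric",
        nSamples     = "integer",
        nPhenotypes  = "integer",
        effectSize   = "numeric",
        correlation  = "numeric",
        family       = "character",
        nReplicates  = "integer",
        seed         = "integer"),
    prototype(
        alleleFreq   = 0.3,
        nSamples     = 300L,
        nPhenotypes  = 10L,
        effectSize   = 1.2,
        correlation  = 0.5,
        family       = "normal",
        nReplicates  = 10000L,
        seed         = 1L))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    p <- object@alleleFreq
    m <- object@nPhenotypes
    r <- object@correlation
    if (length(p) != 1L || !is.finite(p) || p <= 0 || p >= 1)
        msg <- c(msg, "'alleleFreq' must be a single value in (0, 1)")
    if (object@nSamples < 1L)
        msg <- c(msg, "'nSamples' must be a positive integer")
    if (m < 1L)
        msg <- c(msg, "'nPhenotypes' must be a positive integer")
    if (!is.finite(object@effectSize) || object@effectSize <= 0)
        msg <- c(msg, "'effectSize' must be > 0")
    if (m > 1L && (r <= -1 / (m - 1) || r >= 1))
        msg <- c(msg, sprintf(
            "'correlation' must lie in (-1/(m-1), 1) = (%.4f, 1) for m = %d",
            -1 / (m - 1), m))
    if (!object@family %in% c("normal", "lognormal", "chisq"))
        msg <- c(msg, "'family' must be one of normal, lognormal, chisq")
    if (object@nReplicates < 1L)
        msg <- c(msg, "'nReplicates' must be a positive integer")
    if (length(msg)) msg else TRUE
})

#' @param alleleFreq,nSamples,nPhenotypes,effectSize,correlation,family,nReplicates,seed
#'   see slot documentation.
#' @rdname SimulationConfig-class
SimulationConfig <- function(alleleFreq = 0.3, nSamples = 300,
                             nPhenotypes = 10, effectSize = 1.2,
                             correlation = 0.5, family = "normal",
                             nReplicates = 10000, seed = 1) {
    new("SimulationConfig",
        alleleFreq = as.numeric(alleleFreq),
        nSamples = as.integer(nSamples),
        nPhenotypes = as.integer(nPhenotypes),
        effectSize = as.numeric(effectSize),
        correlation = as.numeric(correlation),
        family = as.character(family),
        nReplicates = as.integer(nReplicates),
        seed = as.integer(seed))
}

#' Result of one association method applied to one SNP
#'
#' @slot method one of "one_by_one", "permutation", "manova", "pca".
#' @slot statistic the method's summary statistic: the minimum per-trait
#'   p-value (P_min) for the two univariate strategies, Pillai's trace or
#'   Wilks' lambda for MANOVA, the F statistic for single-PC regression.
#' @slot pValue the per-SNP p-value in [0, 1].
#' @slot perTraitP per-trait p-values (one_by_one and permutation only;
#'   empty otherwise).
#' @slot nUsed number of samples entering the test after missing-data
#'   handling.
#'
#' @export AssociationResult
#' @exportClass AssociationResult
setClass("AssociationResult",
    representation(
        method    = "character",
        statistic = "numeric",
        pValue    = "numeric",
        perTraitP = "numeric",
        nUsed     = "integer"))

setValidity("AssociationResult", function(object) {
    msg <- character()
    if (!object@method %in% .MPAT_METHODS)
        msg <- c(msg, "unknown 'method'")
    if (length(object@pValue) != 1L || is.na(object@pValue) ||
        object@pValue < 0 || object@pValue > 1)
        msg <- c(msg, "'pValue' must be a single value in [0, 1]")
    if (length(object@perTraitP) &&
        any(object@perTraitP < 0 | object@perTraitP > 1, na.rm = TRUE))
        msg <- c(msg, "'perTraitP' entries must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' @rdname AssociationResult-class
AssociationResult <- function(method, statistic, pValue,
                              perTraitP = numeric(), nUsed) {
    new("AssociationResult", method = method,
        statistic = as.numeric(statistic), pValue = as.numeric(pValue),
        perTraitP = as.numeric(perTraitP), nUsed = as.integer(nUsed))
}

#' Empirical power (or size) of one method at one design point
#'
#' @slot method method identifier.
#' @slot config the \linkS4class{SimulationConfig} the estimate refers to.
#' @slot threshold the p-value cutoff used for rejection.
#' @slot power empirical rejection proportion in [0, 1].
#' @slot mcSE binomial Monte-Carlo standard error
#'   \code{sqrt(power * (1 - power) / nReplicates)}.
#' @slot nReplicates number of replicates behind the estimate.
#'
#' @export PowerEstimate
#' @exportClass PowerEstimate
setClass("PowerEstimate",
    representation(
        method      = "character",
        config      = "SimulationConfig",
        threshold   = "numeric",
        power       = "numeric",
        mcSE        = "numeric",
        nReplicates = "integer"))

setValidity("PowerEstimate", function(object) {
    msg <- character()
    if (object@threshold <= 0 || object@threshold >= 1)
        msg <- c(msg, "'threshold' must lie in (0, 1)")
    if (object@power < 0 || object@power > 1)
        msg <- c(msg, "'power' must lie in [0, 1]")
    se <- sqrt(object@power * (1 - object@power) / object@nReplicates)
    if (!isTRUE(all.equal(se, object@mcSE, tolerance = 1e-8)))
        msg <- c(msg, "'mcSE' inconsistent with power and nReplicates")
    if (length(msg)) msg else TRUE
})

PowerEstimate <- function(method, config, threshold, power, nReplicates) {
    new("PowerEstimate", method = method, config = config,
        threshold = as.numeric(threshold), power = as.numeric(power),
        mcSE = sqrt(power * (1 - power) / nReplicates),
        nReplicates = as.integer(nReplicates))
}

#' A candidate-SNP study: genotype and phenotype tables joined on sample ID
#'
#' Genotypes are stored as allele-A counts (0/1/2, NA = missing) in a
#' samples x SNPs integer matrix; phenotypes as a samples x traits numeric
#' matrix. Rows of the two matrices are aligned on the shared sample IDs.
#'
#' @slot genotypes integer matrix, samples x SNPs, entries 0/1/2/NA.
#' @slot phenotypes numeric matrix, samples x traits.
#'
#' @export CandidateStudy
#' @exportClass CandidateStudy
setClass("CandidateStudy",
    representation(
        genotypes  = "matrix",
        phenotypes = "matrix"))

setValidity("CandidateStudy", function(object) {
    msg <- character()
    G <- object@genotypes
    Y <- object@phenotypes
    if (nrow(G) != nrow(Y))
        msg <- c(msg, "genotype and phenotype tables differ in sample count")
    if (!identical(rownames(G), rownames(Y)))
        msg <- c(msg, "genotype and phenotype rows must share sample IDs")
    if (is.null(rownames(G)) || anyDuplicated(rownames(G)))
        msg <- c(msg, "sample IDs must be present and unique")
    bad <- !(G %in% c(0L, 1L, 2L) | is.na(G))
    if (any(bad))
        msg <- c(msg, "genotype entries must be 0, 1, 2 or NA")
    if (!is.numeric(Y))
        msg <- c(msg, "phenotypes must be numeric")
    if (length(msg)) msg else TRUE
})

CandidateStudy <- function(genotypes, phenotypes) {
    storage.mode(genotypes) <- "integer"
    storage.mode(phenotypes) <- "double"
    new("CandidateStudy", genotypes = genotypes, phenotypes = phenotypes)
}

#' Per-SNP, per-method ranking of a candidate study
#'
#' @slot results data.frame with one row per (snp, method): snp, method,
#'   statistic, p_value, n_used. Failed SNP/method combinations carry NA.
#' @slot rBar mean pairwise trait correlation on complete phenotype rows.
#' @slot nComplete number of complete phenotype rows.
#' @slot topK integer, how many top SNPs \code{topSNPs} reports per method.
#'
#' @exportClass RankingReport
setClass("RankingReport",
    representation(
        results   = "data.frame",
        rBar      = "numeric",
        nComplete = "integer",
        topK      = "integer"))

setValidity("RankingReport", function(object) {
    need <- c("snp", "method", "statistic", "p_value", "n_used")
    if (!all(need %in% names(object@results)))
        return(paste("results must contain columns:",
                     paste(need, collapse = ", ")))
    TRUE
})
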