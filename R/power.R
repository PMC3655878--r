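## Monte-Carlo engine: null-calibrated significance thresholds and
## empirical power estimation over grids of the design parameters.

## Replicate contexts keep the calibration and evaluation replicate sets
## independent even though they share one root seed.
.CTX_CALIBRATE <- 1L
.CTX_POWER     <- 2L

## p-values of the requested methods over R independent replicates of
## `config`. One dataset per replicate, shared by all methods (paired
## comparisons). Returns an R x length(methods) matrix. Replicates where a
## method fails (e.g. a monomorphic genotype draw at tiny n) yield NA.
.replicatePvalues <- function(config, methods, R, B = 200L,
                              mode = "regression", k = 1L,
                              statistic = "pillai", context = .CTX_POWER) {
    methods <- .matchMethods(methods)
    out <- matrix(NA_real_, R, length(methods),
                  dimnames = list(NULL, methods))
    for (rep_ in seq_len(R)) {
        set.seed(.spawnSeed(config@seed, rep_, context))
        g <- simulateGenotypes(config@nSamples, config@alleleFreq)
        Y <- simulatePhenotypes(g, config)
        for (meth in methods) {
            out[rep_, meth] <- tryCatch(
                pValue(associationTest(Y, g, method = meth, mode = mode,
                                       B = B, k = k, statistic = statistic)),
                error = function(e) NA_real_)
        }
    }
    if (anyNA(out))
        warning(sum(is.na(out)), " replicate/method p-values failed (NA)")
    out
}

#' Calibrate a method's significance threshold under the null
#'
#' Simulates \code{nNull} replicates of the null model (delta = 1),
#' computes the method's p-value on each, and returns the empirical
#' alpha-quantile of those p-values using the lower (order-statistic)
#' convention: the \code{ceiling(alpha * nNull)}-th smallest p-value. The
#' rejection rule \code{p <= threshold} then has empirical size alpha on
#' the calibration set, which puts methods with conservative or
#' anti-conservative nominal p-values on an equal type-I-error footing.
#'
#' @param method one of "one_by_one", "permutation", "manova", "pca".
#' @param configNull a \linkS4class{SimulationConfig} with
#'   \code{effectSize = 1}.
#' @param alpha target type-I error level (default 0.05).
#' @param nNull number of null replicates (default 1000).
#' @param B permutations per replicate for the permutation method.
#' @param mode,k,statistic method options, see \code{\link{associationTest}}.
#' @return the calibrated threshold, a single value in (0, 1).
#' @export
calibrateThreshold <- function(method, configNull, alpha = 0.05,
                               nNull = 1000L, B = 200L, mode = "regression",
                               k = 1L, statistic = "pillai") {
    stopifnot(is(configNull, "SimulationConfig"))
    if (configNull@effectSize != 1)
        stop("'configNull' must have effectSize = 1 (the null model)")
    if (nNull < 100L) stop("'nNull' must be at least 100")
    p <- .replicatePvalues(configNull, method, R = as.integer(nNull), B = B,
                           mode = mode, k = k, statistic = statistic,
                           context = .CTX_CALIBRATE)[, 1L]
    .lowerQuantile(p[!is.na(p)], alpha)
}

#' Estimate empirical power of a method at a design point
#'
#' Simulates \code{nReplicates(config)} independent datasets and reports
#' the fraction whose p-value is at or below \code{threshold}, with its
#' binomial Monte-Carlo standard error. With \code{effectSize = 1} this is
#' the method's empirical size. The replicate stream is independent of the
#' one \code{\link{calibrateThreshold}} uses, so a calibrated threshold is
#' evaluated out of sample. Deterministic given the config's seed.
#'
#' @param method one of "one_by_one", "permutation", "manova", "pca".
#' @param config a \linkS4class{SimulationConfig}.
#' @param threshold rejection cutoff in (0, 1), typically from
#'   \code{\link{calibrateThreshold}}.
#' @param B,mode,k,statistic method options, see
#'   \code{\link{associationTest}}.
#' @return a \linkS4class{PowerEstimate}.
#' @export
estimatePower <- function(method, config, threshold, B = 200L,
                          mode = "regression", k = 1L,
                          statistic = "pillai") {
    stopifnot(is(config, "SimulationConfig"))
    if (threshold <= 0 || threshold >= 1)
        stop("'threshold' must lie in (0, 1)")
    method <- match.arg(method, .MPAT_METHODS)
    p <- .replicatePvalues(config, method, R = config@nReplicates, B = B,
                           mode = mode, k = k, statistic = statistic,
                           context = .CTX_POWER)[, 1L]
    p <- p[!is.na(p)]
    PowerEstimate(method, config, threshold,
                  power = mean(p <= threshold), nReplicates = length(p))
}

.VARY_SLOTS <- c(correlation = "correlation", n_phenotypes = "nPhenotypes",
                 n_samples = "nSamples", effect_size = "effectSize",
                 nPhenotypes = "nPhenotypes", nSamples = "nSamples",
                 effectSize = "effectSize")

#' Empirical power over a grid of one design parameter
#'
#' For each grid value, rebuilds the design, recalibrates every method's
#' threshold on a matched null (same n, m, r and allele frequency,
#' delta = 1), then estimates power on an independent replicate set at the
#' alternative. All methods share each replicate's dataset, so
#' between-method comparisons are paired. Bit-reproducible given the base
#' config's seed.
#'
#' @param methods character vector of method names, or "all".
#' @param baseConfig a \linkS4class{SimulationConfig}; its
#'   \code{nReplicates} is the power replicate count.
#' @param vary which parameter the grid walks: "correlation",
#'   "n_phenotypes", "n_samples" or "effect_size".
#' @param values grid values for that parameter.
#' @param alpha type-I error level for calibration (default 0.05).
#' @param nNull null replicates per grid point for calibration.
#' @param B,mode,k,statistic method options, see
#'   \code{\link{associationTest}}.
#' @return a tidy \code{data.frame} with one row per (method, grid value):
#'   columns method, parameter, value, threshold, power, mc_se,
#'   n_replicates.
#' @export
powerGrid <- function(methods, baseConfig, vary, values, alpha = 0.05,
                      nNull = 1000L, B = 200L, mode = "regression", k = 1L,
                      statistic = "pillai") {
    stopifnot(is(baseConfig, "SimulationConfig"))
    if (!vary %in% names(.VARY_SLOTS))
        stop("'vary' must be one of: correlation, n_phenotypes, ",
             "n_samples, effect_size")
    slotName <- .VARY_SLOTS[[vary]]
    methods <- .matchMethods(methods)
    rows <- vector("list", length(values) * length(methods))
    i <- 0L
    for (v in values) {
        cfg <- baseConfig
        slot(cfg, slotName) <- if (slotName %in% c("nPhenotypes", "nSamples"))
            as.integer(v) else as.numeric(v)
        validObject(cfg)
        nullCfg <- cfg
        nullCfg@effectSize <- 1
        pNull <- .replicatePvalues(nullCfg, methods, R = as.integer(nNull),
                                   B = B, mode = mode, k = k,
                                   statistic = statistic,
                                   context = .CTX_CALIBRATE)
        pAlt <- .replicatePvalues(cfg, methods, R = cfg@nReplicates, B = B,
                                  mode = mode, k = k, statistic = statistic,
                                  context = .CTX_POWER)
        for (meth in methods) {
            thr <- .lowerQuantile(stats::na.omit(pNull[, meth]), alpha)
            pm <- stats::na.omit(pAlt[, meth])
            pw <- mean(pm <= thr)
            i <- i + 1L
            rows[[i]] <- data.frame(
                method = meth, parameter = vary, value = v, threshold = thr,
                power = pw,
                mc_se = sqrt(pw * (1 - pw) / length(pm)),
                n_replicates = length(pm))
        }
    }
    do.call(rbind, rows)
}
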