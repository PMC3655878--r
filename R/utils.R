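## Internal helpers: per-replicate seeding, quantile convention, config IO,
## plus accessor and show methods for the S4 classes.

.M31 <- 2147483647  # 2^31 - 1, Mersenne prime used by the seed hash

## Derive an isolated, reproducible seed for replicate `k` of a run rooted
## at `seed`. `context` separates independent replicate sets that share a
## root seed (e.g. threshold calibration vs power evaluation). All
## arithmetic stays below 2^53 so it is exact in doubles.
.spawnSeed <- function(seed, k, context = 0L) {
    s <- (abs(as.numeric(seed)) %% .M31)
    h <- (s * 48271 + as.numeric(k) * 2654435.0 + as.numeric(context) *
          69621) %% .M31
    h <- (h * 16807 + 12345) %% .M31
    as.integer(h)
}

## Lower empirical quantile: the ceiling(alpha * n)-th order statistic.
.lowerQuantile <- function(x, alpha) {
    k <- max(1L, as.integer(ceiling(alpha * length(x))))
    sort(x, partial = k)[k]
}

.matchMethods <- function(methods) {
    if (identical(methods, "all")) return(.MPAT_METHODS)
    m <- match.arg(methods, .MPAT_METHODS, several.ok = TRUE)
    unique(m)
}

#' Read a simulation configuration from a YAML or JSON file
#'
#' Keys mirror the \linkS4class{SimulationConfig} fields:
#' \code{allele_freq}, \code{n_samples}, \code{n_phenotypes},
#' \code{effect_size}, \code{correlation}, \code{family},
#' \code{n_replicates}, \code{seed} (camelCase variants are accepted too).
#' Missing keys fall back to the constructor defaults.
#'
#' @param path path to a YAML (or JSON, a YAML subset) configuration file.
#' @return a \linkS4class{SimulationConfig}.
#' @export
readSimulationConfig <- function(path) {
    raw <- yaml::read_yaml(path)
    key <- function(a, b) if (!is.null(raw[[a]])) raw[[a]] else raw[[b]]
    args <- list(
        alleleFreq  = key("allele_freq", "alleleFreq"),
        nSamples    = key("n_samples", "nSamples"),
        nPhenotypes = key("n_phenotypes", "nPhenotypes"),
        effectSize  = key("effect_size", "effectSize"),
        correlation = key("correlation", "correlation"),
        family      = key("family", "family"),
        nReplicates = key("n_replicates", "nReplicates"),
        seed        = key("seed", "seed"))
    do.call(SimulationConfig, args[!vapply(args, is.null, logical(1))])
}

## ---- accessors ------------------------------------------------------------

#' @describeIn SimulationConfig-class allele-A frequency.
#' @param x an object of the documented class.
setMethod("alleleFreq", "SimulationConfig", function(x) x@alleleFreq)
#' @describeIn SimulationConfig-class number of individuals n.
setMethod("nSamples", "SimulationConfig", function(x) x@nSamples)
#' @describeIn SimulationConfig-class number of traits m.
setMethod("nPhenotypes", "SimulationConfig", function(x) x@nPhenotypes)
#' @describeIn SimulationConfig-class per-allele effect delta.
setMethod("effectSize", "SimulationConfig", function(x) x@effectSize)
#' @describeIn SimulationConfig-class common trait correlation r.
setMethod("traitCorrelation", "SimulationConfig", function(x) x@correlation)
#' @describeIn SimulationConfig-class marginal trait family.
setMethod("distFamily", "SimulationConfig", function(x) x@family)
#' @describeIn SimulationConfig-class replicate count R.
setMethod("nReplicates", "SimulationConfig", function(x) x@nReplicates)
#' @describeIn SimulationConfig-class root seed.
setMethod("randomSeed", "SimulationConfig", function(x) x@seed)

#' @describeIn AssociationResult-class method identifier.
#' @param x an object of the documented class.
setMethod("assocMethod", "AssociationResult", function(x) x@method)
#' @describeIn AssociationResult-class summary statistic.
setMethod("statistic", "AssociationResult", function(x) x@statistic)
#' @describeIn AssociationResult-class per-SNP p-value.
setMethod("pValue", "AssociationResult", function(x) x@pValue)
#' @describeIn AssociationResult-class per-trait p-values (may be empty).
setMethod("perTraitP", "AssociationResult", function(x) x@perTraitP)
#' @describeIn AssociationResult-class samples used after missing-data
#'   handling.
setMethod("nUsed", "AssociationResult", function(x) x@nUsed)

#' @describeIn PowerEstimate-class method identifier.
#' @param x an object of the documented class.
setMethod("assocMethod", "PowerEstimate", function(x) x@method)
#' @describeIn PowerEstimate-class rejection threshold used.
setMethod("threshold", "PowerEstimate", function(x) x@threshold)
#' @describeIn PowerEstimate-class empirical rejection proportion.
setMethod("powerValue", "PowerEstimate", function(x) x@power)
#' @describeIn PowerEstimate-class binomial Monte-Carlo standard error.
setMethod("mcSE", "PowerEstimate", function(x) x@mcSE)
#' @describeIn PowerEstimate-class replicate count.
setMethod("nReplicates", "PowerEstimate", function(x) x@nReplicates)

#' @describeIn CandidateStudy-class samples x SNPs allele-count matrix.
#' @param x an object of the documented class.
setMethod("genotypes", "CandidateStudy", function(x) x@genotypes)
#' @describeIn CandidateStudy-class samples x traits matrix.
setMethod("phenotypes", "CandidateStudy", function(x) x@phenotypes)
#' @describeIn CandidateStudy-class shared sample identifiers.
setMethod("sampleIDs", "CandidateStudy", function(x) rownames(x@genotypes))

#' @describeIn RankingReport-class full (snp, method) result table.
#' @param x an object of the documented class.
setMethod("rankings", "RankingReport", function(x) x@results)
#' @describeIn RankingReport-class mean pairwise trait correlation.
setMethod("meanTraitCorrelation", "RankingReport", function(x) x@rBar)

#' @describeIn RankingReport-class top-k SNPs per method, sorted by
#'   ascending p-value with ties broken by SNP label.
#' @param method restrict to one method (default: all).
#' @param k number of SNPs to report (default: the report's topK).
#' @param ... unused.
setMethod("topSNPs", "RankingReport", function(x, method = NULL, k = NULL,
                                               ...) {
    k <- if (is.null(k)) x@topK else as.integer(k)
    res <- x@results
    meth <- if (is.null(method)) unique(res$method) else method
    out <- lapply(meth, function(mm) {
        d <- res[res$method == mm, , drop = FALSE]
        d <- d[order(d$p_value, d$snp), , drop = FALSE]
        utils::head(d, k)
    })
    names(out) <- meth
    if (length(out) == 1L) out[[1L]] else out
})

## ---- show methods ---------------------------------------------------------

#' @export
setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig\n",
        sprintf("  allele A frequency : %.3f\n", object@alleleFreq),
        sprintf("  samples (n)        : %d\n", object@nSamples),
        sprintf("  phenotypes (m)     : %d\n", object@nPhenotypes),
        sprintf("  effect size (delta): %.3f%s\n", object@effectSize,
                if (object@effectSize == 1) "  [null]" else ""),
        sprintf("  trait correlation  : %.3f\n", object@correlation),
        sprintf("  family             : %s\n", object@family),
        sprintf("  replicates / seed  : %d / %d\n",
                object@nReplicates, object@seed), sep = "")
})

#' @export
setMethod("show", "AssociationResult", function(object) {
    cat(sprintf("AssociationResult [%s]\n", object@method),
        sprintf("  statistic : %.4g\n", object@statistic),
        sprintf("  p-value   : %.4g\n", object@pValue),
        sprintf("  n used    : %d\n", object@nUsed), sep = "")
    if (length(object@perTraitP))
        cat("  per-trait p:",
            paste(signif(object@perTraitP, 3), collapse = " "), "\n")
})

#' @export
setMethod("show", "PowerEstimate", function(object) {
    cat(sprintf("PowerEstimate [%s]\n", object@method),
        sprintf("  threshold : %.5f\n", object@threshold),
        sprintf("  power     : %.4f (MC SE %.4f, R = %d)\n",
                object@power, object@mcSE, object@nReplicates), sep = "")
})

#' @export
setMethod("show", "CandidateStudy", function(object) {
    cat(sprintf("CandidateStudy: %d samples, %d SNPs, %d traits\n",
                nrow(object@genotypes), ncol(object@genotypes),
                ncol(object@phenotypes)))
    miss <- colMeans(is.na(object@genotypes))
    cat(sprintf("  genotype missingness: %.1f%% - %.1f%% per SNP\n",
                100 * min(miss), 100 * max(miss)))
    cat(sprintf("  complete phenotype rows: %d\n",
                sum(stats::complete.cases(object@phenotypes))))
})

#' @export
setMethod("show", "RankingReport", function(object) {
    cat(sprintf(
        "RankingReport: %d SNPs x %d methods, rBar = %.2f, n = %d\n",
        length(unique(object@results$snp)),
        length(unique(object@results$method)),
        object@rBar, object@nComplete))
    tops <- topSNPs(object)
    if (is.data.frame(tops)) tops <- list(tops)
    for (d in tops) {
        cat(sprintf("  %-11s", paste0(d$method[1L], ":")),
            paste(sprintf("%s (%.3g)", d$snp, d$p_value), collapse = "  "),
            "\n")
    }
})
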