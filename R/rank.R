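#' Rank candidate SNPs by each association method
#'
#' Runs every requested method on every SNP of a study and reports, per
#' method, the SNPs sorted by ascending p-value (ties broken by SNP
#' label). Per-SNP failures (e.g. a monomorphic SNP) are caught, reported
#' as NA rows and do not abort the run. The report also carries the mean
#' pairwise trait correlation computed on complete phenotype rows (the
#' study-level "r bar" summary).
#'
#' @param study a \linkS4class{CandidateStudy}.
#' @param methods character vector of method names, or "all" (default).
#' @param mode per-trait genotype coding ("regression"/"anova").
#' @param B permutations for the permutation method.
#' @param k PCs for the PCA method (1 or 2).
#' @param statistic MANOVA statistic ("pillai"/"wilks").
#' @param seed root seed for the permutation streams (one derived stream
#'   per SNP, so results do not depend on SNP column order).
#' @param topK how many top SNPs \code{\link{topSNPs}} reports per method.
#' @return a \linkS4class{RankingReport}.
#' @examples
#' fx <- makeFixture("tiny", seed = 7, outPrefix = tempfile())
#' st <- readStudy(fx["genotypes"], fx["phenotypes"], quiet = TRUE)
#' rankSNPs(st, methods = c("one_by_one", "pca"), seed = 1)
#' @export
rankSNPs <- function(study, methods = "all", mode = "regression", B = 1000L,
                     k = 1L, statistic = "pillai", seed = 1L, topK = 5L) {
    stopifnot(is(study, "CandidateStudy"))
    methods <- .matchMethods(methods)
    G <- genotypes(study)
    Y <- phenotypes(study)
    snps <- colnames(G)
    rows <- vector("list", length(snps) * length(methods))
    i <- 0L
    for (snp in snps) {
        g <- G[, snp]
        ## seed tied to the SNP name, not its column position
        snpSeed <- .spawnSeed(seed, sum(utf8ToInt(snp)))
        for (meth in methods) {
            res <- tryCatch(
                associationTest(Y, g, method = meth, mode = mode, B = B,
                                k = k, statistic = statistic,
                                seed = snpSeed),
                error = function(e) {
                    warning(sprintf("SNP '%s', method '%s' failed: %s",
                                    snp, meth, conditionMessage(e)),
                            call. = FALSE)
                    NULL
                })
            i <- i + 1L
            rows[[i]] <- if (is.null(res)) {
                data.frame(snp = snp, method = meth, statistic = NA_real_,
                           p_value = NA_real_, n_used = NA_integer_)
            } else {
                data.frame(snp = snp, method = meth,
                           statistic = res@statistic, p_value = pValue(res),
                           n_used = nUsed(res))
            }
        }
    }
    results <- do.call(rbind, rows)
    ok <- stats::complete.cases(Y)
    cm <- stats::cor(Y[ok, , drop = FALSE])
    rBar <- if (ncol(Y) > 1L) mean(cm[upper.tri(cm)]) else 1
    new("RankingReport", results = results, rBar = rBar,
        nComplete = sum(ok), topK = as.integer(topK))
}

#' Write a ranking report as a tidy TSV
#'
#' One row per (snp, method) with columns snp, method, statistic, p_value,
#' n_used, sorted by method then ascending p-value.
#'
#' @param report a \linkS4class{RankingReport}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeRankingReport <- function(report, path) {
    stopifnot(is(report, "RankingReport"))
    d <- rankings(report)
    d <- d[order(d$method, d$p_value, d$snp), ]
    utils::write.table(d, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Pretty-print the top-k table in the wide per-method layout
#'
#' Formats the top SNPs per method as alternating SNP / p-value lines, the
#' layout typically used to present the leading candidates of each method
#' side by side.
#'
#' @param report a \linkS4class{RankingReport}.
#' @param k SNPs per method (default: the report's topK).
#' @return character vector of formatted lines, invisibly; also printed.
#' @export
formatTopTable <- function(report, k = NULL) {
    stopifnot(is(report, "RankingReport"))
    tops <- topSNPs(report, k = k)
    if (is.data.frame(tops)) tops <- list(tops)
    lines <- c(sprintf("Mean trait correlation rBar = %.2f; n = %d",
                       meanTraitCorrelation(report), report@nComplete))
    for (d in tops) {
        lines <- c(lines,
                   paste(c(sprintf("%-12s", d$method[1L]),
                           sprintf("%10s", d$snp)), collapse = "\t"),
                   paste(c(sprintf("%-12s", ""),
                           sprintf("%10.3g", d$p_value)), collapse = "\t"))
    }
    cat(lines, sep = "\n")
    invisible(lines)
}
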