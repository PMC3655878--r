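#' Generate a synthetic candidate-SNP study on disk
#'
#' Writes a genotype table, a phenotype table and a ground-truth sidecar
#' describing which SNPs carry a planted association. Two profiles:
#'
#' \describe{
#'   \item{"schizophrenia_like"}{456 samples (216 coded as patients, 240
#'     as controls in the sidecar), 51 candidate SNPs with per-SNP missing
#'     genotype rates drawn uniformly in [0.21, 0.56], 5 quantitative
#'     traits with common pairwise correlation 0.59 — the scale of a
#'     typical candidate-gene endophenotype study. One SNP (by default)
#'     carries a planted multiplicative effect \code{delta} on all traits;
#'     the remaining SNPs are null with allele frequencies uniform in
#'     [0.1, 0.5].}
#'   \item{"tiny"}{12 samples, 2 SNPs, 2 traits, no missingness —
#'     unit-test scale.}
#' }
#'
#' The sidecar \code{<prefix>.truth.tsv} lists, per SNP, the allele-A
#' frequency, the planted delta (1 = null) and the realized missing rate,
#' plus a per-sample group column ("patient"/"control") in
#' \code{<prefix>.groups.tsv} for the schizophrenia_like profile. All
#' output is byte-identical for a given seed.
#'
#' @param profile "schizophrenia_like" or "tiny".
#' @param seed integer seed.
#' @param outPrefix path prefix for the output files.
#' @param delta planted per-allele effect for associated SNPs
#'   (default 1.3).
#' @param nAssoc number of associated SNPs planted (default 1; the first
#'   \code{nAssoc} SNP labels).
#' @param missingRange optional length-2 vector overriding the profile's
#'   per-SNP missing-genotype rate range (e.g. \code{c(0, 0)} for complete
#'   genotypes).
#' @return named character vector of the written file paths
#'   (\code{genotypes}, \code{phenotypes}, \code{truth}, and
#'   \code{groups} where applicable).
#' @examples
#' fx <- makeFixture("tiny", seed = 1, outPrefix = tempfile())
#' read.delim(fx["truth"])
#' @export
makeFixture <- function(profile = c("schizophrenia_like", "tiny"),
                        seed = 1L, outPrefix = "fixture", delta = 1.3,
                        nAssoc = 1L, missingRange = NULL) {
    profile <- match.arg(profile)
    set.seed(as.integer(seed))
    if (profile == "schizophrenia_like") {
        n <- 456L; nSnp <- 51L; m <- 5L; r <- 0.59
        missRange <- c(0.21, 0.56)
        groups <- c(rep("patient", 216L), rep("control", 240L))
    } else {
        n <- 12L; nSnp <- 2L; m <- 2L; r <- 0.5
        missRange <- c(0, 0)
        groups <- NULL
    }
    if (!is.null(missingRange)) {
        stopifnot(length(missingRange) == 2L, all(missingRange >= 0),
                  all(missingRange < 1))
        missRange <- missingRange
    }
    ids <- sprintf("S%03d", seq_len(n))
    snps <- sprintf("snp%02d", seq_len(nSnp))
    traits <- paste0("T", seq_len(m))
    nAssoc <- min(as.integer(nAssoc), nSnp)
    isAssoc <- seq_len(nSnp) <= nAssoc
    freqs <- ifelse(isAssoc, 0.3, stats::runif(nSnp, 0.1, 0.5))
    missRates <- stats::runif(nSnp, missRange[1L], missRange[2L])

    G <- vapply(seq_len(nSnp), function(j)
        simulateGenotypes(n, freqs[j]), integer(n))
    dimnames(G) <- list(ids, snps)

    ## phenotypes: one shared equicorrelated noise term; planted SNPs add
    ## their multiplicative genotype means (in sum, for nAssoc > 1)
    R <- chol(equicorrMatrix(m, r))
    Y <- matrix(stats::rnorm(n * m), n, m) %*% R
    for (j in which(isAssoc))
        Y <- Y + (genotypeMean(G[, j], delta) - 1)
    Y <- Y + 1
    dimnames(Y) <- list(ids, traits)

    Gmiss <- G
    for (j in seq_len(nSnp))
        Gmiss[stats::runif(n) < missRates[j], j] <- NA

    study <- CandidateStudy(Gmiss, round(Y, 6))
    paths <- writeStudy(study, outPrefix)
    truth <- data.frame(snp = snps, allele_freq = round(freqs, 4),
                        delta = ifelse(isAssoc, delta, 1),
                        missing_rate = round(colMeans(is.na(Gmiss)), 4))
    tf <- paste0(outPrefix, ".truth.tsv")
    utils::write.table(truth, tf, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, truth = tf)
    if (!is.null(groups)) {
        gf <- paste0(outPrefix, ".groups.tsv")
        utils::write.table(data.frame(sample_id = ids, group = groups),
                           gf, sep = "\t", quote = FALSE, row.names = FALSE)
        paths <- c(paths, groups = gf)
    }
    paths
}
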