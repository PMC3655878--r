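## Tab-delimited genotype/phenotype readers and writers. First column of
## each table is the sample ID; "NA" (or empty) marks missing cells.
## Genotype cells are allele counts 0/1/2 or two-letter strings such as
## "AA"/"AG"/"GG".

## Parse one SNP column of genotype tokens into allele-A counts. String
## tokens are counted against a reference allele; by default the
## alphabetically first allele observed at the SNP is taken as allele A.
.parseGenoColumn <- function(tok, snp, refAllele = NULL) {
    tok <- trimws(as.character(tok))
    tok[tok == "" | tok == "NA"] <- NA
    out <- rep(NA_integer_, length(tok))
    seen <- !is.na(tok)
    if (!any(seen)) return(out)
    numeric_like <- grepl("^[012]$", tok[seen])
    if (all(numeric_like)) {
        out[seen] <- as.integer(tok[seen])
        return(out)
    }
    if (any(numeric_like))
        stop(sprintf("SNP '%s': mixed numeric and string genotype coding",
                     snp))
    bad <- seen & !grepl("^[A-Za-z]{2}$", tok)
    if (any(bad))
        stop(sprintf("unparseable genotype token '%s' at row %d of SNP '%s'",
                     tok[which(bad)[1L]], which(bad)[1L], snp))
    alleles <- sort(unique(unlist(strsplit(tok[seen], ""))))
    if (length(alleles) > 2L)
        stop(sprintf("SNP '%s' has more than two alleles: %s", snp,
                     paste(alleles, collapse = ", ")))
    ref <- if (is.null(refAllele)) alleles[1L] else refAllele
    cnt <- vapply(strsplit(tok[seen], ""),
                  function(a) sum(a == ref), integer(1))
    out[seen] <- cnt
    out
}

.readTable <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    d <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
    if (ncol(d) < 2L)
        stop("expected a sample-ID column plus data columns in ", path)
    ids <- d[[1L]]
    if (anyDuplicated(ids))
        stop("duplicated sample IDs in ", path)
    rownames(d) <- ids
    d[, -1L, drop = FALSE]
}

#' Read a candidate-SNP study from genotype and phenotype tables
#'
#' Both files are tab-delimited with a header row; the first column holds
#' sample IDs and "NA" (or an empty cell) marks missing values. Genotypes
#' may be coded as allele counts 0/1/2 or as two-letter strings
#' ("AA", "AG", ...); for string coding, allele A of each SNP defaults to
#' the alphabetically first allele observed. Samples are joined on the
#' intersection of the two ID sets. Per-SNP missing rates and per-trait
#' completeness are reported via \code{message()}.
#'
#' @param genoPath path to the genotype table (samples x SNPs).
#' @param phenoPath path to the phenotype table (samples x traits).
#' @param refAlleles optional named character vector, SNP -> reference
#'   (allele A) letter, overriding the alphabetical default.
#' @param keepSamples optional character vector restricting the study to a
#'   subset of sample IDs (e.g. patients only).
#' @param quiet suppress the per-column completeness messages.
#' @return a \linkS4class{CandidateStudy}.
#' @export
readStudy <- function(genoPath, phenoPath, refAlleles = NULL,
                      keepSamples = NULL, quiet = FALSE) {
    gd <- .readTable(genoPath)
    pd <- .readTable(phenoPath)
    ids <- intersect(rownames(gd), rownames(pd))
    if (!is.null(keepSamples)) ids <- intersect(ids, keepSamples)
    if (length(ids) == 0L)
        stop("no overlapping sample IDs between the two tables")
    gd <- gd[ids, , drop = FALSE]
    pd <- pd[ids, , drop = FALSE]
    G <- vapply(colnames(gd), function(snp)
        .parseGenoColumn(gd[[snp]], snp, refAlleles[snp]),
        integer(length(ids)))
    dimnames(G) <- list(ids, colnames(gd))
    suppressWarnings(Y <- vapply(pd, as.numeric, numeric(length(ids))))
    badcol <- colSums(is.na(Y) & !(pd == "NA" | pd == "" | is.na(pd))) > 0
    if (any(badcol))
        stop("non-numeric phenotype values in column(s): ",
             paste(colnames(pd)[badcol], collapse = ", "))
    dimnames(Y) <- list(ids, colnames(pd))
    if (!quiet) {
        miss <- colMeans(is.na(G))
        message(sprintf("read %d samples, %d SNPs, %d traits",
                        length(ids), ncol(G), ncol(Y)))
        message(sprintf("per-SNP missing genotype rate: %s",
                        paste(sprintf("%s=%.2f", colnames(G), miss),
                              collapse = ", ")))
        message(sprintf("per-trait completeness: %s",
                        paste(sprintf("%s=%.2f", colnames(Y),
                                      1 - colMeans(is.na(Y))),
                              collapse = ", ")))
    }
    CandidateStudy(G, Y)
}

#' Write a study's genotype and phenotype tables
#'
#' Inverse of \code{\link{readStudy}}: writes \code{<prefix>.geno.tsv}
#' (allele counts 0/1/2) and \code{<prefix>.pheno.tsv}, tab-delimited with
#' a header and "NA" for missing cells.
#'
#' @param study a \linkS4class{CandidateStudy}.
#' @param prefix output path prefix.
#' @return invisibly, the two file paths.
#' @export
writeStudy <- function(study, prefix) {
    stopifnot(is(study, "CandidateStudy"))
    gf <- paste0(prefix, ".geno.tsv")
    pf <- paste0(prefix, ".pheno.tsv")
    gd <- data.frame(sample_id = sampleIDs(study), genotypes(study),
                     check.names = FALSE)
    pd <- data.frame(sample_id = sampleIDs(study), phenotypes(study),
                     check.names = FALSE)
    utils::write.table(gd, gf, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(pd, pf, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(c(genotypes = gf, phenotypes = pf))
}
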