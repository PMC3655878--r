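## The four per-SNP association strategies. Each reduces an n x m trait
## matrix Y and a genotype vector g (allele-A counts 0/1/2) to a single
## p-value.

## Vectorized per-trait tests of the columns of Y against each column of G
## (a matrix whose columns are genotype vectors sharing one multiset of
## values, e.g. permutations of one g). Returns an m x B matrix of
## p-values. Complete data only.
##
## regression: F-test (1 df) for the slope of y on the allele count.
## anova:      one-way F-test (k-1 df) of genotype-group means, k = number
##             of genotype groups observed.
## Constant trait columns get p = 1 by convention.
.traitPvalMatrix <- function(Y, G, mode = c("regression", "anova")) {
    mode <- match.arg(mode)
    n <- nrow(Y)
    cs <- colSums(Y)
    Syy <- colSums(Y * Y) - cs^2 / n          # total sum of squares, per trait
    const <- Syy <= 1e-12 * pmax(1, abs(cs^2 / n))
    g1 <- G[, 1L]
    if (length(unique(g1)) < 2L)
        stop("fewer than 2 genotype groups present")
    if (mode == "regression") {
        Sxx <- sum(g1^2) - sum(g1)^2 / n      # identical for every column of G
        Gc <- G - rep(colMeans(G), each = n)
        Sxy <- crossprod(Y, Gc)               # m x B
        r2 <- Sxy^2 / outer(Syy, rep(Sxx, ncol(G)))
        r2 <- pmin(r2, 1)
        Fst <- (n - 2) * r2 / pmax(1 - r2, .Machine$double.eps)
        P <- stats::pf(Fst, 1, n - 2, lower.tail = FALSE)
    } else {
        lev <- sort(unique(g1))
        k <- length(lev)
        SSB <- matrix(0, ncol(Y), ncol(G))
        corr <- cs^2 / n
        for (l in lev) {
            I <- (G == l) + 0
            nl <- sum(g1 == l)                # group size, same per column
            SSB <- SSB + crossprod(Y, I)^2 / nl
        }
        SSB <- SSB - corr
        SSW <- pmax(Syy - SSB, 0)
        Fst <- (SSB / (k - 1)) / pmax(SSW / (n - k),
                                      .Machine$double.eps * pmax(Syy, 1))
        P <- stats::pf(Fst, k - 1, n - k, lower.tail = FALSE)
    }
    P[const, ] <- 1
    attr(P, "F") <- Fst
    P
}

## Single-trait test on complete pairs; core of traitAssocTest.
.traitTest <- function(y, g, mode = c("regression", "anova")) {
    mode <- match.arg(mode)
    ok <- !is.na(y) & !is.na(g)
    y <- y[ok]; g <- g[ok]
    n <- length(y)
    if (n < 3L || length(unique(paste(y, g))) < 3L)
        stop("need at least 3 distinct complete observations")
    P <- .traitPvalMatrix(cbind(y), cbind(g), mode)
    k <- length(unique(g))
    df <- if (mode == "regression") c(1, n - 2) else c(k - 1, n - k)
    list(F = attr(P, "F")[1L], p = P[1L], df = df, n = n)
}

#' Test one quantitative trait against one SNP
#'
#' Either a simple linear regression of the trait on the allele count
#' (F-test with 1 df, matching an additive genotype coding) or a one-way
#' ANOVA across the observed genotype groups (k-1 df). Complete pairs only.
#' A constant trait yields p = 1 by convention; fewer than two genotype
#' groups is an error.
#'
#' @param y numeric trait vector.
#' @param g integer allele-A counts (0/1/2), same length; NA allowed.
#' @param mode "regression" (default) or "anova".
#' @return an object of class \code{"htest"} with the F statistic, degrees
#'   of freedom, p-value and \code{n.used}.
#' @examples
#' g <- rep(0:2, each = 20)
#' y <- g + rnorm(60)
#' traitAssocTest(y, g)
#' @export
traitAssocTest <- function(y, g, mode = c("regression", "anova")) {
    mode <- match.arg(mode)
    tt <- .traitTest(y, g, mode)
    structure(class = "htest", list(
        statistic = c(F = tt$F),
        parameter = c(df1 = tt$df[1L], df2 = tt$df[2L]),
        p.value = tt$p,
        n.used = tt$n,
        method = sprintf("Single-trait genotype association (%s)", mode),
        data.name = deparse(substitute(y))))
}

## Rows usable by the complete-case methods: non-missing genotype and a
## fully observed trait vector.
.completeRows <- function(Y, g) {
    if (length(g) != nrow(Y))
        stop("length of 'g' must equal nrow(Y)")
    !is.na(g) & stats::complete.cases(Y)
}

#' Per-trait tests with Bonferroni correction ("one at a time")
#'
#' Tests each trait separately against the SNP and summarizes the SNP by
#' the smallest per-trait p-value P_min. The reported p-value is the
#' Bonferroni-adjusted \code{min(1, m * P_min)}, so comparing it to a level
#' alpha is equivalent to comparing P_min to alpha / m. Each trait uses its
#' own pairwise-complete samples, so a value missing in one trait does not
#' discard the others.
#'
#' @param Y numeric matrix, samples x traits.
#' @param g integer allele-A counts (0/1/2), NA = missing.
#' @param mode per-trait test, "regression" (default) or "anova".
#' @return an \linkS4class{AssociationResult}; \code{statistic} is P_min,
#'   \code{perTraitP} the per-trait p-values.
#' @export
oneByOneTest <- function(Y, g, mode = c("regression", "anova")) {
    mode <- match.arg(mode)
    Y <- as.matrix(Y)
    if (length(g) != nrow(Y)) stop("length of 'g' must equal nrow(Y)")
    m <- ncol(Y)
    pt <- vapply(seq_len(m), function(j) .traitTest(Y[, j], g, mode)$p,
                 numeric(1))
    names(pt) <- colnames(Y)
    pmin_ <- min(pt)
    used <- !is.na(g) & rowSums(!is.na(Y)) > 0
    AssociationResult("one_by_one", statistic = pmin_,
                      pValue = min(1, m * pmin_),
                      perTraitP = pt, nUsed = sum(used))
}

## All permutations of seq_len(n), as an n! x n matrix (n <= 8 guard).
.allPerms <- function(n) {
    if (n > 8L) stop("exhaustive enumeration supported for n <= 8 only")
    if (n == 1L) return(matrix(1L, 1L, 1L))
    sub <- .allPerms(n - 1L)
    out <- matrix(0L, n * nrow(sub), n)
    row <- 1L
    for (i in seq_len(n)) {
        rest <- seq_len(n)[-i]
        idx <- row:(row + nrow(sub) - 1L)
        out[idx, 1L] <- i
        out[idx, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
        row <- row + nrow(sub)
    }
    out
}

#' Permutation min-p test
#'
#' The SNP's summary statistic is P_min, the smallest per-trait p-value.
#' Its null distribution is estimated by permuting the sample labels of the
#' trait matrix as a block (equivalently, permuting the genotype vector)
#' so that trait intercorrelation is preserved while any genotype-trait
#' association is destroyed. The p-value is
#' \code{(1 + #\{permuted P_min <= observed\}) / (B + 1)}, which cannot be
#' zero and is valid under exchangeability; ties count as "<=". With
#' \code{exact = TRUE} (n <= 8) all n! row orderings are enumerated and the
#' exact tail proportion is returned instead.
#'
#' Complete-case rows (genotype and all traits observed) only.
#'
#' @param Y numeric matrix, samples x traits.
#' @param g integer allele-A counts (0/1/2), NA = missing.
#' @param B number of random permutations (>= 100 unless \code{exact}).
#' @param mode per-trait test, "regression" (default) or "anova".
#' @param seed optional seed for the permutation stream; NULL = current RNG.
#' @param exact enumerate all permutations instead of sampling.
#' @return an \linkS4class{AssociationResult}; \code{statistic} is the
#'   observed P_min, \code{perTraitP} the per-trait p-values.
#' @export
permutationMinP <- function(Y, g, B = 1000L, mode = c("regression", "anova"),
                            seed = NULL, exact = FALSE) {
    mode <- match.arg(mode)
    Y <- as.matrix(Y)
    ok <- .completeRows(Y, g)
    Y <- Y[ok, , drop = FALSE]
    g <- g[ok]
    n <- length(g)
    if (n < 10L && !exact) stop("need at least 10 complete-case samples")
    if (!exact && B < 100L) stop("'B' must be at least 100")
    Pobs <- .traitPvalMatrix(Y, cbind(g), mode)
    obs <- min(Pobs)
    if (exact) {
        perms <- .allPerms(n)
        Gp <- matrix(g[t(perms)], n, nrow(perms))
        Pminb <- apply(.traitPvalMatrix(Y, Gp, mode), 2L, min)
        pval <- mean(Pminb <= obs)
        B <- nrow(perms)
    } else {
        if (!is.null(seed)) set.seed(as.integer(seed))
        Gp <- vapply(seq_len(B), function(b) sample(g), numeric(n))
        Pminb <- apply(.traitPvalMatrix(Y, Gp, mode), 2L, min)
        pval <- (1 + sum(Pminb <= obs)) / (B + 1)
    }
    AssociationResult("permutation", statistic = obs, pValue = pval,
                      perTraitP = as.numeric(Pobs), nUsed = n)
}

## Detect (and name) a collinear trait pair so singular-covariance errors
## are actionable.
.namesCollinear <- function(Y) {
    cm <- suppressWarnings(stats::cor(Y))
    cm[!is.finite(cm)] <- 0
    diag(cm) <- 0
    idx <- which(abs(cm) > 1 - 1e-10, arr.ind = TRUE)
    if (nrow(idx)) {
        nm <- colnames(Y)
        if (is.null(nm)) nm <- paste0("trait", seq_len(ncol(Y)))
        sprintf("'%s' and '%s'", nm[idx[1L, 1L]], nm[idx[1L, 2L]])
    } else "some traits"
}

#' One-way MANOVA of the trait matrix on genotype
#'
#' Tests equality of the multivariate trait means across the observed
#' genotype groups, using Pillai's trace (default, the more robust choice)
#' or Wilks' lambda with the standard F approximation. With a single trait
#' this collapses to the one-way ANOVA F-test. Complete-case rows only.
#'
#' @param Y numeric matrix, samples x traits.
#' @param g integer allele-A counts (0/1/2), NA = missing.
#' @param statistic "pillai" (default) or "wilks".
#' @return an \linkS4class{AssociationResult}; \code{statistic} is the
#'   Pillai trace / Wilks lambda (or the F statistic when m = 1).
#' @export
manovaTest <- function(Y, g, statistic = c("pillai", "wilks")) {
    statistic <- match.arg(statistic)
    Y <- as.matrix(Y)
    ok <- .completeRows(Y, g)
    Y <- Y[ok, , drop = FALSE]
    g <- g[ok]
    n <- nrow(Y)
    m <- ncol(Y)
    gf <- factor(g)
    k <- nlevels(gf)
    if (k < 2L) stop("fewer than 2 genotype groups present")
    if (m == 1L) {
        tt <- .traitTest(Y[, 1L], g, "anova")
        return(AssociationResult("manova", statistic = tt$F, pValue = tt$p,
                                 nUsed = n))
    }
    if (n <= m + k)
        stop("need more complete-case samples than traits + genotype groups")
    E <- stats::cov(Y - rowsum(Y, gf)[gf, , drop = FALSE] /
                        as.vector(table(gf))[gf])
    if (qr(E)$rank < m)
        stop("residual trait covariance is singular; ",
             .namesCollinear(Y), " are collinear")
    fit <- stats::manova(Y ~ gf)
    sm <- summary(fit,
                  test = if (statistic == "pillai") "Pillai" else "Wilks")
    row <- sm$stats["gf", ]
    AssociationResult("manova", statistic = unname(row[2L]),
                      pValue = unname(row["Pr(>F)"]), nUsed = n)
}

#' Principal-component scores of a trait matrix
#'
#' PCA of the column-standardized traits (correlation-matrix PCA), so each
#' trait enters with weight inversely proportional to its standard
#' deviation. Components are ordered by decreasing variance; each loading
#' column's sign is fixed so that its sum is non-negative. Complete rows
#' only; rows with any missing trait are dropped (their score rows are NA).
#'
#' @param Y numeric matrix, samples x traits.
#' @param k number of components to return (<= number of traits).
#' @param scale standardize columns (default TRUE); FALSE gives
#'   covariance-matrix PCA.
#' @return list with \code{scores} (n x k, NA rows where Y was incomplete),
#'   \code{loadings} (m x k, orthonormal), \code{varianceExplained}
#'   (length k) and \code{complete} (logical row mask used).
#' @export
pcScores <- function(Y, k = 1L, scale = TRUE) {
    Y <- as.matrix(Y)
    m <- ncol(Y)
    k <- as.integer(k)
    if (k < 1L || k > m) stop("'k' must be between 1 and the trait count")
    ok <- stats::complete.cases(Y)
    Yc <- Y[ok, , drop = FALSE]
    if (nrow(Yc) <= m) stop("need more complete rows than traits")
    sds <- apply(Yc, 2L, stats::sd)
    if (any(sds == 0))
        stop("zero-variance trait: ",
             paste(colnames(Y)[sds == 0], collapse = ", "))
    pr <- stats::prcomp(Yc, center = TRUE, scale. = scale)
    sgn <- sign(colSums(pr$rotation[, seq_len(k), drop = FALSE]))
    sgn[sgn == 0] <- 1
    loadings <- sweep(pr$rotation[, seq_len(k), drop = FALSE], 2L, sgn, `*`)
    scores <- matrix(NA_real_, nrow(Y), k,
                     dimnames = list(rownames(Y), paste0("PC", seq_len(k))))
    scores[ok, ] <- sweep(pr$x[, seq_len(k), drop = FALSE], 2L, sgn, `*`)
    list(scores = scores, loadings = loadings,
         varianceExplained = pr$sdev[seq_len(k)]^2 / sum(pr$sdev^2),
         complete = ok)
}

#' Association test on leading principal components
#'
#' Condenses the trait matrix into its first principal component (k = 1)
#' and runs the single-trait test on the scores, or takes the first two
#' components (k = 2) and tests them jointly through the multivariate
#' (MANOVA / multivariate regression) machinery with Pillai's trace.
#' Complete-case rows (genotype and all traits) only.
#'
#' @param Y numeric matrix, samples x traits.
#' @param g integer allele-A counts (0/1/2), NA = missing.
#' @param k 1 (default) or 2 principal components.
#' @param mode genotype coding for the score test: "regression" (allele
#'   count, 1 df; default) or "anova" (genotype as a factor).
#' @return an \linkS4class{AssociationResult}; \code{statistic} is the F
#'   statistic (k = 1) or Pillai's trace (k = 2).
#' @export
pcaTest <- function(Y, g, k = 1L, mode = c("regression", "anova")) {
    mode <- match.arg(mode)
    k <- as.integer(k)
    if (!k %in% c(1L, 2L)) stop("'k' must be 1 or 2")
    Y <- as.matrix(Y)
    ok <- .completeRows(Y, g)
    Yc <- Y[ok, , drop = FALSE]
    gc_ <- g[ok]
    n <- length(gc_)
    if (ncol(Y) == 1L && k == 2L) stop("'k' = 2 needs at least 2 traits")
    pcs <- pcScores(Yc, k = min(k, ncol(Yc)))
    if (k == 1L) {
        tt <- .traitTest(pcs$scores[, 1L], gc_, mode)
        return(AssociationResult("pca", statistic = tt$F, pValue = tt$p,
                                 nUsed = n))
    }
    S <- pcs$scores
    x <- if (mode == "anova") factor(gc_) else gc_
    if (length(unique(gc_)) < 2L) stop("fewer than 2 genotype groups present")
    fit <- stats::manova(S ~ x)
    sm <- summary(fit, test = "Pillai")
    row <- sm$stats["x", ]
    AssociationResult("pca", statistic = unname(row[2L]),
                      pValue = unname(row["Pr(>F)"]), nUsed = n)
}

#' Run one of the four association strategies
#'
#' Thin dispatcher used by the power engine and the SNP-ranking workflow.
#'
#' @param Y numeric matrix, samples x traits.
#' @param g integer allele-A counts (0/1/2), NA = missing.
#' @param method one of "one_by_one", "permutation", "manova", "pca".
#' @param mode per-trait genotype coding ("regression"/"anova").
#' @param B permutations for the permutation method.
#' @param k number of PCs for the PCA method (1 or 2).
#' @param statistic MANOVA statistic ("pillai"/"wilks").
#' @param seed optional seed for the permutation stream.
#' @return an \linkS4class{AssociationResult}.
#' @export
associationTest <- function(Y, g,
                            method = c("one_by_one", "permutation",
                                       "manova", "pca"),
                            mode = "regression", B = 1000L, k = 1L,
                            statistic = "pillai", seed = NULL) {
    method <- match.arg(method)
    switch(method,
        one_by_one  = oneByOneTest(Y, g, mode),
        permutation = permutationMinP(Y, g, B = B, mode = mode, seed = seed),
        manova      = manovaTest(Y, g, statistic = statistic),
        pca         = pcaTest(Y, g, k = k, mode = mode))
}
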