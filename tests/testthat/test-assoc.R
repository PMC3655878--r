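test_that("perfect trait-genotype association gives vanishing p-values", {
    g <- rep(0:2, times = 20)
    y <- as.numeric(g)
    for (mode in c("regression", "anova")) {
        tt <- traitAssocTest(y, g, mode)
        expect_lt(tt$p.value, 1e-10)
    }
    ## near-perfect multivariate case through every method
    set.seed(1)
    Y <- cbind(g + rnorm(60, sd = 1e-4), g + rnorm(60, sd = 1e-4))
    expect_lt(pValue(oneByOneTest(Y, g)), 1e-10)
    expect_lt(pValue(manovaTest(Y, g)), 1e-10)
    expect_lt(pValue(pcaTest(Y, g)), 1e-10)
})

test_that("single-trait F and p match the brute-force decomposition", {
    ## small printed fixture, n = 9
    y <- c(2.1, 1.7, 2.4, 3.0, 2.8, 3.3, 4.1, 3.6, 4.4)
    g <- c(0L, 0L, 0L, 1L, 1L, 1L, 2L, 2L, 2L)
    tt <- traitAssocTest(y, g, "anova")
    oracle <- bruteAnova(y, g)
    expect_equal(unname(tt$statistic), oracle$F, tolerance = 1e-12)
    expect_equal(tt$p.value, oracle$p, tolerance = 1e-12)
    expect_identical(tt$n.used, 9L)
    ## regression mode against the standard linear-model fit
    tr <- traitAssocTest(y, g, "regression")
    fit <- summary(lm(y ~ g))
    expect_equal(unname(tr$statistic), unname(fit$fstatistic[1]),
                 tolerance = 1e-10)
    expect_equal(tr$p.value,
                 unname(pf(fit$fstatistic[1], 1, 7, lower.tail = FALSE)),
                 tolerance = 1e-10)
})

test_that("single-trait edge contracts hold", {
    g <- rep(0:2, each = 4)
    expect_equal(traitAssocTest(rep(5, 12), g)$p.value, 1)
    expect_error(traitAssocTest(rnorm(12), rep(1L, 12)),
                 "genotype groups")
    ## missing values fall back to complete pairs
    y <- c(NA, rnorm(11))
    expect_identical(traitAssocTest(y, g)$n.used, 11L)
})

test_that("null single-trait p-values are uniform", {
    n <- 60
    set.seed(5)
    g <- simulateGenotypes(n, 0.3)
    for (mode in c("regression", "anova")) {
        ps <- vapply(seq_len(2000), function(i)
            traitAssocTest(rnorm(n), g, mode)$p.value, numeric(1))
        expect_gt(ks.test(ps, punif)$p.value, 0.01)
    }
})

test_that("Bonferroni summary is min(1, m * min p) on per-trait tests", {
    set.seed(7)
    g <- simulateGenotypes(80, 0.3)
    Y <- oracleMVN(80, 3, 0.4)
    res <- oneByOneTest(Y, g)
    pt <- perTraitP(res)
    expect_length(pt, 3)
    expect_equal(statistic(res), min(pt))
    expect_equal(pValue(res), min(1, 3 * min(pt)))
    ## per-trait values agree with independent single-trait fits
    expect_equal(unname(pt), apply(Y, 2, function(y)
        traitAssocTest(y, g)$p.value), tolerance = 1e-12)
    ## m = 1: Bonferroni is the identity
    r1 <- oneByOneTest(Y[, 1, drop = FALSE], g)
    expect_equal(pValue(r1), traitAssocTest(Y[, 1], g)$p.value)
    ## cap at 1 for a deliberately null, high-p draw
    set.seed(8)
    Yn <- matrix(rnorm(80 * 4), 80)
    rn <- oneByOneTest(Yn, g)
    expect_lte(pValue(rn), 1)
    if (min(perTraitP(rn)) > 0.25) expect_equal(pValue(rn), 1)
})

test_that("per-trait tests use pairwise-complete samples", {
    set.seed(9)
    g <- simulateGenotypes(50, 0.4)
    Y <- oracleMVN(50, 2, 0.3)
    Y[1:10, 1] <- NA
    res <- oneByOneTest(Y, g)
    expect_equal(perTraitP(res)[1],
                 traitAssocTest(Y[11:50, 1], g[11:50])$p.value,
                 ignore_attr = TRUE)
    expect_equal(perTraitP(res)[2], traitAssocTest(Y[, 2], g)$p.value,
                 ignore_attr = TRUE)
})

test_that("exhaustive permutation equals full enumeration", {
    set.seed(11)
    n <- 6
    g <- c(0L, 0L, 1L, 1L, 2L, 2L)
    Y <- oracleMVN(n, 2, 0.3, mu = 1 + 0.5 * rep(g, 1))
    res <- permutationMinP(Y, g, mode = "regression", exact = TRUE)
    ## oracle: all 720 row orderings, per-trait p via plain lm fits
    perms <- oraclePerms(n)
    obs <- bruteMinP(Y, g)
    tail <- mean(apply(perms, 1, function(ix) bruteMinP(Y, g[ix]) <= obs))
    expect_equal(pValue(res), tail, tolerance = 1e-12)
    expect_equal(statistic(res), obs, tolerance = 1e-12)
})

test_that("permutation p matches the single-trait p when m = 1", {
    set.seed(13)
    n <- 50
    g <- simulateGenotypes(n, 0.3)
    y <- matrix(rnorm(n), ncol = 1)
    B <- 4000
    res <- permutationMinP(y, g, B = B, seed = 17)
    p0 <- traitAssocTest(y[, 1], g)$p.value
    expect_lt(abs(pValue(res) - p0), 4 * sqrt(p0 * (1 - p0) / B))
})

test_that("perfect association attains the permutation floor 1/(B+1)", {
    g <- rep(0:2, times = 10)
    Y <- cbind(as.numeric(g), as.numeric(g))
    res <- permutationMinP(Y, g, B = 199, seed = 3)
    expect_equal(pValue(res), 1 / 200)
})

test_that("permutation input contracts are enforced", {
    set.seed(15)
    g <- simulateGenotypes(30, 0.3)
    Y <- matrix(rnorm(60), 30)
    expect_error(permutationMinP(Y, g, B = 50), "at least 100")
    expect_error(permutationMinP(Y[1:8, ], g[1:8], B = 200),
                 "at least 10 complete-case")
})

test_that("MANOVA matches the explicit H/E eigen-computation", {
    set.seed(17)
    n <- 40
    g <- rep(c(0L, 1L, 2L), c(15, 15, 10))
    Y <- oracleMVN(n, 3, 0.4, mu = 1 + 0.3 * g)
    res <- manovaTest(Y, g, statistic = "pillai")
    oracle <- brutePillai(Y, g)
    expect_equal(statistic(res), oracle$pillai, tolerance = 1e-10)
    expect_equal(pValue(res), oracle$p, tolerance = 1e-10)
    expect_identical(nUsed(res), 40L)
    ## Wilks variant agrees with the standard summary
    rw <- manovaTest(Y, g, statistic = "wilks")
    sm <- summary(manova(Y ~ factor(g)), test = "Wilks")$stats
    expect_equal(statistic(rw), unname(sm[1, 2]), tolerance = 1e-10)
})

test_that("MANOVA collapses to ANOVA for a single trait", {
    set.seed(19)
    g <- simulateGenotypes(60, 0.3)
    y <- rnorm(60) + 0.3 * g
    res <- manovaTest(cbind(y), g)
    expect_equal(pValue(res), traitAssocTest(y, g, "anova")$p.value,
                 tolerance = 1e-12)
})

test_that("MANOVA names collinear traits on singular covariance", {
    set.seed(21)
    g <- simulateGenotypes(40, 0.3)
    y <- rnorm(40)
    Y <- cbind(a = y, b = 2 * y, c = rnorm(40))
    expect_error(manovaTest(Y, g), "collinear")
    expect_error(manovaTest(Y, g), "'a'")
    expect_error(manovaTest(Y, g), "'b'")
})

test_that("PC scores reproduce the correlation-matrix eigenstructure", {
    set.seed(23)
    ## m = 1: PC1 is the standardized trait
    y <- rnorm(30, mean = 5, sd = 3)
    pcs <- pcScores(cbind(y), k = 1)
    expect_equal(unname(pcs$scores[, 1]), as.numeric(scale(y)),
                 tolerance = 1e-10)
    ## duplicated trait + tiny noise: PC1 explains ~ everything
    y2 <- cbind(y, y + rnorm(30, sd = 1e-4))
    expect_gt(pcScores(y2, k = 2)$varianceExplained[1], 0.999)
    ## equicorrelated population: leading eigenvalue -> 1 + (m-1) r
    n <- 1e4
    Y <- oracleMVN(n, 10, 0.5, mu = rep(0, n))
    pc <- pcScores(Y, k = 2)
    expect_equal(pc$varianceExplained[1] * 10, 1 + 9 * 0.5,
                 tolerance = 0.15)
    ## loadings orthonormal, sign convention: non-negative column sums
    expect_equal(crossprod(pc$loadings), diag(2), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_true(all(colSums(pc$loadings) >= 0))
    expect_error(pcScores(cbind(rep(1, 30), rnorm(30))), "zero-variance")
})

test_that("PCA test collapses to the single-trait test when m = 1", {
    set.seed(25)
    g <- simulateGenotypes(70, 0.3)
    y <- rnorm(70) + 0.2 * g
    res <- pcaTest(cbind(y), g, k = 1)
    expect_equal(pValue(res), traitAssocTest(as.numeric(scale(y)), g)$p.value,
                 tolerance = 1e-12)
})

test_that("two-PC variant runs the joint multivariate test", {
    set.seed(27)
    g <- simulateGenotypes(100, 0.3)
    Y <- oracleMVN(100, 4, 0.3, mu = 1 + 0.25 * g)
    r2 <- pcaTest(Y, g, k = 2)
    expect_true(pValue(r2) >= 0 && pValue(r2) <= 1)
    expect_identical(assocMethod(r2), "pca")
    expect_error(pcaTest(cbind(rnorm(100)), g, k = 2), "2 traits")
    expect_error(pcaTest(Y, g, k = 3), "1 or 2")
})

test_that("all methods are invariant under joint sample reordering", {
    set.seed(29)
    n <- 60
    g <- simulateGenotypes(n, 0.3)
    Y <- oracleMVN(n, 3, 0.5, mu = 1 + 0.2 * g)
    ix <- sample(n)
    for (meth in c("one_by_one", "manova", "pca")) {
        p1 <- pValue(associationTest(Y, g, method = meth))
        p2 <- pValue(associationTest(Y[ix, ], g[ix], method = meth))
        expect_equal(p1, p2, tolerance = 1e-10, label = meth)
    }
    ## permutation: exact enumeration is order-free
    g6 <- c(0L, 1L, 2L, 0L, 1L, 2L)
    Y6 <- oracleMVN(6, 2, 0.3)
    ix6 <- c(4L, 2L, 6L, 1L, 3L, 5L)
    expect_equal(pValue(permutationMinP(Y6, g6, exact = TRUE)),
                 pValue(permutationMinP(Y6[ix6, ], g6[ix6], exact = TRUE)),
                 tolerance = 1e-12)
})

test_that("positive rescaling of a trait leaves every method unchanged", {
    set.seed(31)
    n <- 50
    g <- simulateGenotypes(n, 0.3)
    Y <- oracleMVN(n, 3, 0.4, mu = 1 + 0.2 * g)
    Ys <- Y
    Ys[, 2] <- 1000 * Ys[, 2]
    for (meth in c("one_by_one", "manova", "pca")) {
        expect_equal(pValue(associationTest(Y, g, method = meth)),
                     pValue(associationTest(Ys, g, method = meth)),
                     tolerance = 1e-8, label = meth)
    }
    g6 <- c(0L, 1L, 2L, 0L, 1L, 2L)
    Y6 <- Y[1:6, ]
    Y6s <- Y6; Y6s[, 1] <- 7 * Y6s[, 1]
    expect_equal(pValue(permutationMinP(Y6, g6, exact = TRUE)),
                 pValue(permutationMinP(Y6s, g6, exact = TRUE)),
                 tolerance = 1e-12)
})

test_that("complete-case methods drop rows with any missing value", {
    set.seed(33)
    n <- 80
    g <- simulateGenotypes(n, 0.3)
    Y <- oracleMVN(n, 3, 0.4)
    Y[1:5, 2] <- NA
    g[6:8] <- NA
    keep <- 9:80
    expect_identical(nUsed(manovaTest(Y, g)), length(keep))
    expect_equal(pValue(manovaTest(Y, g)),
                 pValue(manovaTest(Y[keep, ], g[keep])), tolerance = 1e-12)
    expect_identical(nUsed(pcaTest(Y, g)), length(keep))
    expect_identical(nUsed(permutationMinP(Y, g, B = 100, seed = 1)),
                     length(keep))
})
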