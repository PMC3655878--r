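## Independent brute-force oracles used across the test files. These
## deliberately avoid the package's internal code paths.

## One-way ANOVA by explicit sum-of-squares decomposition.
bruteAnova <- function(y, g) {
    n <- length(y)
    groups <- split(y, g)
    k <- length(groups)
    grand <- mean(y)
    ssb <- sum(vapply(groups, function(v) length(v) * (mean(v) - grand)^2,
                      numeric(1)))
    ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
    F <- (ssb / (k - 1)) / (ssw / (n - k))
    list(F = F, p = pf(F, k - 1, n - k, lower.tail = FALSE))
}

## Between- and within-group SSCP matrices by explicit group sums, and the
## Pillai trace tr(H (H+E)^-1) with its F approximation.
brutePillai <- function(Y, g) {
    Y <- as.matrix(Y)
    n <- nrow(Y)
    m <- ncol(Y)
    lev <- sort(unique(g))
    k <- length(lev)
    grand <- colMeans(Y)
    H <- matrix(0, m, m)
    E <- matrix(0, m, m)
    for (l in lev) {
        Yl <- Y[g == l, , drop = FALSE]
        d <- colMeans(Yl) - grand
        H <- H + nrow(Yl) * tcrossprod(d)
        R <- sweep(Yl, 2, colMeans(Yl))
        E <- E + crossprod(R)
    }
    V <- sum(diag(H %*% solve(H + E)))
    s <- min(m, k - 1)
    mm <- (abs(m - k + 1) - 1) / 2
    nn <- (n - k - m - 1) / 2
    F <- (2 * nn + s + 1) / (2 * mm + s + 1) * V / (s - V)
    df1 <- s * (2 * mm + s + 1)
    df2 <- s * (2 * nn + s + 1)
    list(pillai = V, F = F,
         p = pf(F, df1, df2, lower.tail = FALSE))
}

## Per-trait minimum p-value using plain lm/anova fits (slow, independent).
bruteMinP <- function(Y, g, mode = "regression") {
    ps <- apply(as.matrix(Y), 2, function(y) {
        if (mode == "regression") {
            fit <- summary(lm(y ~ g))
            unname(pf(fit$fstatistic[1], fit$fstatistic[2],
                      fit$fstatistic[3], lower.tail = FALSE))
        } else {
            anova(lm(y ~ factor(g)))[["Pr(>F)"]][1]
        }
    })
    min(ps)
}

## All permutations of 1..n, built by simple insertion (independent of the
## package's enumeration).
oraclePerms <- function(n) {
    perms <- list(1L)
    for (i in 2:n) {
        perms <- unlist(lapply(perms, function(p) {
            lapply(0:(i - 1L), function(pos) append(p, i, after = pos))
        }), recursive = FALSE)
    }
    do.call(rbind, perms)
}

## Quick equicorrelated MVN sample with genotype mean shifts, independent
## of the package generator (used where a raw dataset is all that matters).
oracleMVN <- function(n, m, r, mu = rep(1, n)) {
    L <- chol(outer(seq_len(m), seq_len(m),
                    function(i, j) ifelse(i == j, 1, r)))
    matrix(rnorm(n * m), n, m) %*% L + mu
}
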