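---
title: "Testing a SNP against multiple correlated phenotypes: methods and simulation design"
author: "mpat package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing a SNP against multiple correlated phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpat)
```

# The problem

Complex traits — schizophrenia being the motivating example — are rarely
captured by a single measurement. A study will typically record several
correlated quantitative endophenotypes (IQ subscales, memory scores,
imaging summaries) per subject, together with genotypes at candidate
SNPs. The analyst must decide how to turn an $n \times m$ trait matrix
$Y$ and one genotype vector $g \in \{0,1,2\}^n$ (copies of allele A)
into a single per-SNP significance statement. `mpat` implements the four
standard strategies and a Monte-Carlo framework for comparing their
type-I error and power on an equal footing.

# The generative model

All simulations share one model, fully specified by a
`SimulationConfig`:

* **Genotypes.** The SNP is biallelic with allele-A frequency $p$
  (default 0.3) and in Hardy–Weinberg equilibrium, so each individual's
  allele count is Binomial$(2, p)$ — two independent allele draws. At
  $p = 0.3$ the expected genotype frequencies of AA, AB, BB are 0.09,
  0.42, 0.49.
* **Genotypic effect.** Phenotype means are multiplicative in the
  allele count: BB $\to 1$, AB $\to \delta$, AA $\to \delta^2$. This is
  the quantitative-trait analogue of a genotypic relative risk model;
  $\delta = 1$ is the null of no association. The variance is 1 for
  every trait and genotype, so $\delta$ moves means only.
* **Traits.** Given the genotype, the $m$ traits are multivariate
  normal with every coordinate mean equal to $\delta^{g_i}$ and an
  equicorrelation covariance: unit diagonal, constant off-diagonal $r$.
  The matrix is positive definite iff $-1/(m-1) < r < 1$, which the
  config validates.
* **Non-normal families.** For robustness studies the latent normal
  draw is pushed through a fixed monotone map per cell:
  $\exp(x)$ ("lognormal") or $F^{-1}_{\chi^2_3}(\Phi(x; 1, 1))$
  ("chisq", anchored so that the *null* marginal is exactly
  $\chi^2_3$). Monotone maps preserve ranks, hence the Spearman
  correlation structure and the ordering of the genotype effect. They
  are stand-ins chosen for qualitative realism, not estimates of any
  particular dataset's marginals.

Sampling uses $Z \,\mathrm{chol}(\Sigma)$ with standard-normal $Z$;
replicate $k$ of a run derives its own seed from the root seed through
an integer hash (with a separate "context" constant for calibration
versus evaluation sets), so any replicate is reproducible in isolation
and whole grids are bit-identical under a fixed root seed.

# The four methods

All four consume the same $(Y, g)$ and return an `AssociationResult`
with one p-value.

**One at a time + Bonferroni** (`oneByOneTest`). Each trait is tested
separately — by default a simple linear regression of the trait on the
allele count (F-test, 1 df, matching the multiplicative/ordinal effect
model), optionally a one-way ANOVA across genotype groups (2 df). The
SNP summary is $P_{\min}$, the smallest per-trait p-value, reported as
the Bonferroni-adjusted $\min(1, m P_{\min})$. With correlated traits
this adjustment is conservative. Each trait uses its own
pairwise-complete samples, so a value missing in one trait does not
discard the row for the others.

**Permutation min-p** (`permutationMinP`). The same $P_{\min}$
statistic, but referred to its permutation null: trait rows are
permuted as a block (implemented by permuting $g$, which gives the
identical statistic), preserving trait intercorrelation while
destroying association. The p-value is
$(1 + \#\{P_{\min}^{(b)} \le P_{\min}^{\mathrm{obs}}\})/(B+1)$ — never
zero, valid under exchangeability, ties counted inclusively. For
$n \le 8$ an `exact = TRUE` mode enumerates all $n!$ orderings and
returns the exact tail proportion. Complete-case rows only.

**MANOVA** (`manovaTest`). One-way multivariate analysis of variance of
$Y$ on genotype as a 3-level factor, Pillai's trace by default (the
more robust statistic; Wilks' lambda available), p-value from the
standard F approximation as computed by `stats::manova`. A singular
residual covariance (duplicated trait) is refused with an error naming
the collinear pair. With $m = 1$ the method collapses to the one-way
ANOVA F-test. Complete-case rows only.

**PCA regression** (`pcaTest`). The traits are condensed into their
first principal component — computed on column-standardized traits
(correlation-matrix PCA), so each trait is weighted by the inverse of
its standard deviation — and the PC1 scores are tested like a single
trait. A two-PC variant tests the first two score columns jointly
through the multivariate machinery (Pillai); we chose the joint test
over a min-p across PCs because the score columns are uncorrelated by
construction, making the 2-df joint test the natural generalization.
Loadings carry a deterministic sign convention (non-negative column
sums) so results do not depend on the eigensolver's sign choice.

# Calibrated thresholds

Nominal p-values put the four methods on unequal footings: Bonferroni
is conservative under correlation, MANOVA's F approximation can be
anti-conservative with many traits, and the permutation p-value is
discrete. Power comparisons therefore use **calibrated thresholds**:
for each method and each design point, `calibrateThreshold` simulates
$R_0$ null replicates ($\delta = 1$, same $n, m, r, p$) and returns the
empirical $\alpha$-quantile of the null p-values, using the lower
(order-statistic) convention — the $\lceil \alpha R_0 \rceil$-th
smallest value. The rejection rule $p \le t$ then has empirical size
$\alpha$ on the calibration set. `estimatePower` evaluates the rule on
an *independent* replicate stream (a different seed context), so
thresholds are never assessed in-sample. `powerGrid` repeats
calibration at every grid point, then reports a tidy table of power
with binomial Monte-Carlo standard errors
$\sqrt{\hat\pi(1-\hat\pi)/R}$.

# Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| `alleleFreq` | allele-A frequency | 0.3 | common-variant candidate-SNP regime |
| `effectSize` | per-allele mean multiplier $\delta$ | 1.2 | mid-range effect: informative power differences at $n = 300$ |
| `correlation` | common trait correlation $r$ | 0.5 | typical endophenotype intercorrelation (0.59–0.72 in cognition batteries) |
| `nPhenotypes` | trait count $m$ | 10 | enough traits for multiplicity to bite |
| `nSamples` | subjects $n$ | 300 | candidate-gene study scale |
| `B` (permutations) | min-p null resolution | 1000 (tests), 200 (power grids) | p-granularity $1/(B+1)$; grids only need resolution near 0.05 |
| `alpha` | target size | 0.05 | convention |

# Numerical choices and degenerate inputs

* Threshold quantile: lower order statistic (stated above) — makes
  grids bit-reproducible.
* Permutation estimator: $(b+1)/(B+1)$, inclusive ties.
* A constant trait gets p = 1 by convention; fewer than two observed
  genotype groups is an error (monomorphic SNPs are caught and
  reported as NA rows by the ranking workflow rather than aborting).
* Per-trait F statistics are computed from closed-form sums of squares,
  vectorized across traits and permutations (one BLAS cross-product per
  permutation batch), which is what makes permutation-inside-Monte-Carlo
  grids feasible on one CPU.
* Genotype string tokens ("AG") are counted against a reference
  allele; the default reference is the alphabetically first allele
  observed at the SNP, overridable per SNP (`refAlleles`).
* Missing data: the two univariate strategies use pairwise-complete
  (one-by-one) or complete-case (permutation) rows; MANOVA and PCA
  require complete rows. `nUsed` is always reported. No imputation is
  attempted.

# What the synthetic study generator does and does not emulate

`makeFixture("schizophrenia_like")` writes a 456-sample, 51-SNP,
5-trait study with per-SNP missing-genotype rates uniform in
[0.21, 0.56] and trait equicorrelation 0.59, with one planted
multiplicative association (default $\delta = 1.3$) — the scale and
missingness profile of a real candidate-SNP endophenotype study. It
does **not** emulate linkage disequilibrium between SNPs, covariates,
population structure, family relatedness, non-random missingness, or
trait-specific variances; passing tests on these fixtures therefore
demonstrate correctness of the statistical machinery under the stated
model, not robustness to those real-data complications.

# Problem sizes used by the test suite

The packaged checks run at desk scale, chosen to keep each suite run
in minutes while leaving every assertion's Monte-Carlo tolerance
(3 standard errors) meaningful: size-control sweeps use 500–1,000
calibration and 600–2,000 evaluation replicates; power-ordering grids
use 1,200 replicates per point with 600-replicate calibration;
permutation tests inside grids use $B = 200$. The acceptance script
uses 1,000/2,000 (size) and 1,000/4,000 (power-peak grid) replicates.
Tolerances pool the binomial error of both Monte-Carlo stages wherever
a calibrated threshold is itself estimated.

# Known limitations

* The F approximations behind Pillai/Wilks are asymptotic; at very
  small $n$ with many traits the calibrated-threshold route is the
  reliable one (that is in fact the point of calibration).
* The permutation p-value's lattice ($1/(B+1)$ resolution) makes it
  slightly conservative at small $B$; calibration absorbs this too.
* Correlation-matrix PCA assumes every trait carries signal worth unit
  weight after standardization; a trait that is pure noise dilutes PC1.
* The non-normal families are monotone transforms of one latent
  normal; they do not cover, e.g., heavy-tailed copulas or outlier
  contamination.
* No covariate adjustment, mixed models, or categorical phenotypes.
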