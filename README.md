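# mpat — multi-phenotype association testing for candidate SNPs

Genetic studies of complex traits usually record several correlated
quantitative phenotypes per subject — IQ subscales, memory scores,
blood-pressure components — rather than a single outcome. Given an
n × m trait matrix **Y** and a SNP's allele counts
**g** ∈ {0,1,2}ⁿ, `mpat` answers "is this SNP associated with the
trait battery?" with each of the four standard strategies, and
provides the Monte-Carlo machinery to compare their type-I error and
power fairly. It is aimed at statistical geneticists and
methodologists working with candidate-SNP endophenotype studies.

## The methods

Each strategy maps (Y, g) to one p-value per SNP:

1. **One at a time + Bonferroni** (`oneByOneTest`) — per-trait linear
   regression on the allele count (or one-way ANOVA); the SNP summary
   is P\_min, the smallest per-trait p-value, reported as
   min(1, m · P\_min).
2. **Permutation min-p** (`permutationMinP`) — the same P\_min
   referred to its permutation null (trait rows shuffled as a block,
   preserving trait intercorrelation); p = (1 + #{P\_min⁽ᵇ⁾ ≤
   P\_min})/(B+1), with exact enumeration for n ≤ 8.
3. **MANOVA** (`manovaTest`) — one-way multivariate ANOVA on the
   genotype factor, Pillai's trace (or Wilks' lambda).
4. **PCA regression** (`pcaTest`) — regression of the SNP on the
   first principal component of the standardized traits (or a joint
   test on the first two PCs).

The simulation engine generates genotypes under Hardy–Weinberg
equilibrium (allele frequency p, genotype probabilities p², 2p(1−p),
(1−p)²) and equicorrelated multivariate-normal traits whose means are
1, δ, δ² for BB, AB, AA — a multiplicative per-allele effect; δ = 1 is
the null. `calibrateThreshold` / `estimatePower` / `powerGrid` compare
the methods at per-method thresholds calibrated so every method has
the same empirical type-I error.

## Worked example

One simulated dataset at the default design (n = 300 subjects, m = 10
traits, correlation r = 0.5, effect δ = 1.2), run through all four
methods:

```r
library(mpat)
cfg <- SimulationConfig(nSamples = 300, nPhenotypes = 10,
                        effectSize = 1.2, correlation = 0.5, seed = 1)
d <- simulateDataset(cfg, replicate = 1)
for (m in c("one_by_one", "permutation", "manova", "pca"))
    show(associationTest(d$phenotypes, d$genotypes, method = m,
                         B = 1000, seed = 1))
```

```
AssociationResult [one_by_one]
  statistic : 0.0003531
  p-value   : 0.003531
  n used    : 300
AssociationResult [permutation]
  p-value   : 0.001998
AssociationResult [manova]
  statistic : 0.1055
  p-value   : 0.0454
AssociationResult [pca]
  statistic : 8.365
  p-value   : 0.004107
```

The `statistic` is P\_min for the two univariate strategies, Pillai's
trace for MANOVA and the F statistic for PCA regression. Here every
method detects the planted δ = 1.2 effect, MANOVA only marginally —
with ten traits at r = 0.5 it is the weakest of the four, while PCA
concentrates the shared signal into one component.

A candidate-study workflow on a synthetic 51-SNP table with one
strongly associated SNP planted (δ = 1.6, 21–56% missing genotypes per
SNP):

```r
fx <- makeFixture("schizophrenia_like", seed = 42,
                  outPrefix = tempfile(), delta = 1.6)
st <- readStudy(fx["genotypes"], fx["phenotypes"], quiet = TRUE)
rankSNPs(st, methods = "all", B = 400, seed = 5)
```

```
RankingReport: 51 SNPs x 4 methods, rBar = 0.70, n = 456
  one_by_one: snp01 (1.07e-14)  snp15 (0.00469)  snp39 (0.00831)  ...
  permutation: snp01 (0.00249)  snp15 (0.00499)  snp39 (0.00499)  ...
  manova:     snp01 (5.03e-13)  snp12 (0.00644)  snp15 (0.0576)   ...
  pca:        snp01 (4.56e-18)  snp15 (0.00821)  snp39 (0.0204)   ...
```

All four methods rank the planted `snp01` first; `rBar` is the mean
pairwise trait correlation on complete rows and `n` the joined sample
count. A command-line front end over the same functions lives at
`inst/scripts/mpat.R` (subcommands `simulate`, `test`, `power`,
`rank`, `fixture`).

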