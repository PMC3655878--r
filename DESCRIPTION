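Package: mpat
Title: Multi-Phenotype Association Testing for Candidate SNPs
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Association testing of a single nucleotide polymorphism (SNP)
    against several correlated quantitative phenotypes. Implements four
    strategies that reduce the multi-trait problem to one p-value per SNP:
    per-trait tests with Bonferroni correction, a permutation min-p test,
    one-way MANOVA, and regression on leading principal components of the
    trait matrix. Includes a Monte-Carlo engine that simulates genotypes
    under Hardy-Weinberg equilibrium and equicorrelated multivariate normal
    (or monotone-transformed non-normal) phenotypes under a multiplicative
    genotypic effect model, calibrates per-method significance thresholds so
    that all methods have equal type-I error, and estimates empirical power
    surfaces over correlation, trait count, sample size and effect size.
    Tabular readers, a candidate-SNP ranking workflow and a synthetic study
    generator support analyses of real genotype/phenotype tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, yaml
Suggests: testthat (>= 3.0.0), optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'assoc.R'
    'fixture.R'
    'io.R'
    'mpat-package.R'
    'power.R'
    'rank.R'
    'simulate.R'
    'utils.R'
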