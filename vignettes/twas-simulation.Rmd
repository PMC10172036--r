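---
title: "Simulating TWAS test statistics with twasim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating TWAS test statistics with twasim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The simulation model

`twasim` simulates the full summary-based TWAS pipeline at one cis locus.
A replicate proceeds through five stages, each of which can use its own
LD reference panel:

1. **LD.** A genotype panel (PLINK triplet or synthetic fixture) is
   standardized column-wise and its SNP correlation matrix `R` estimated.
   `R` is shrunk toward the identity, `R* = (R + ε I)/(1 + ε)`, and
   Cholesky-factorized; `R*` parameterizes all downstream sampling.
2. **eQTL architecture.** `n_causal` SNPs are chosen uniformly at random,
   given i.i.d. Gaussian raw effects, and rescaled so that
   `b' R* b = h2g` exactly. Scaling against the same matrix that
   parameterizes genotype sampling makes `h2g` the exact population
   cis-heritability of the genetic expression score `G = X b`.
3. **Expression reference cohort.** `n_qtl` genotype vectors are drawn
   from `MVN(0, R*)`; expression is `G` plus Gaussian noise of variance
   `1 − h2g`, then standardized before model fitting so that penalty
   scales are comparable across `h2g` values.
4. **GWAS.** In *standard mode*, `n_gwas` genotype vectors are drawn the
   same way, the phenotype is built from the trait model, and a marginal
   scan produces per-SNP Wald Z-scores. In *fast mode*, the Z-vector is
   drawn directly from `MVN(√N · R* β, R*)`, the standard
   summary-statistics likelihood regime; memory is `O(P²)` regardless of
   `N`.
5. **TWAS test.** Prediction weights `w` fitted on the expression cohort
   are combined with the GWAS Z-scores under the testing-stage LD:
   `z_TWAS = (w' z)/sqrt(w' R*_test w)`.

### Trait models and their bookkeeping

The phenotype always has population variance 1:

- *causal*: `y = α G/√h2g + ε`, `Var(ε) = 1 − h2ge`. Because `G/√h2g`
  has unit variance, `α² = h2ge` exactly, making `h2ge` directly
  interpretable as the proportion of trait variance explained by
  genetically regulated expression. The sign of `α` is random.
- *null*: `y = ε`, `Var(ε) = 1`.
- *linkage* (horizontal pleiotropy): direct SNP effects `b_link`, drawn
  by the same sparse procedure as the eQTL effects but from an
  independent random stream, act on the trait (`α = 0`). `b_link` is
  scaled against the GWAS-stage LD — the matrix through which those
  effects reach the phenotype — so that `b_link' R* b_link = h2ge`. The
  tested gene then merely *tags* trait signal through LD, the classic
  false-positive mechanism TWAS fine-mapping tries to address.

In fast mode the mean vector uses the small-effect approximation
`E[z] = √N R* β` without a `√(1 − h2ge)` residual shrinkage; the
discrepancy is `O(h2ge)` and the mode-equivalence test verifies that
fast and standard modes agree within Monte-Carlo error at the `h2ge`
scales the simulator targets (≤ a few percent).

## Tunable parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `h2g` | cis-heritability of expression | 0.1 | typical of well-predicted genes |
| `h2ge` | trait variance via expression | 0.01 | power driver; null = 0 |
| `n_causal` | causal eQTLs | 1 | fraction in (0,1) allowed, rounded up |
| `n_gwas` | GWAS sample size | 100,000 | enters fast mode only via `√N` |
| `n_qtl` | eQTL cohort size | 500 | GTEx-scale |
| `ridge_eps` | LD shrinkage ε | 0.1 | logged in the LD object |
| `threshold` | significance level | 2.27e-6 | 0.05/22,000 genes |
| `enet_mixing` | elastic-net α | 0.5 | `1` = LASSO |

## Prediction models

- **LASSO / elastic net** (`glmnet`): penalty chosen by 5-fold
  cross-validation with seeded fold assignment (`lambda.min`); folds are
  the only stochastic element, so fits are reproducible given the seed.
- **GBLUP**: ridge solution `w = (X'X/n + λI)⁻¹ X'y/n` with
  `λ = P(1 − ĥ²)/(n ĥ²)`. `ĥ²` is estimated by maximizing the marginal
  (restricted) likelihood of the standardized-genotype relatedness model
  through the spectrum of `X'X`, rank-filtered so the same code path
  handles `n ≤ P` and collinear SNPs; the estimate is floored at 0.01
  and capped at 0.99. If the optimization fails, a Haseman–Elston
  moment estimate is used with a warning; both estimates are kept in the
  fit diagnostics. `λ` can be fixed directly (`λ = 0` reproduces
  ordinary least squares), which the tests use as an algebraic oracle.
- **true**: the simulated `b` itself, an upper bound for any fitted
  model and the cheapest way to study the test statistic in isolation.
- **external plugins**: an R file defining
  `fit(genotypes, expression) -> weights` is loaded with
  `load_external()` and validated against the contract (length `P`,
  finite). Plugins run in-process without sandboxing, mirroring the
  dynamic-import design this tool family uses. Two examples ship in
  `inst/plugins/`.

All-zero weight vectors (e.g. an over-penalized LASSO) are propagated,
and the TWAS statistic is then reported as *missing*, never as zero;
metric summaries exclude and count these.

## Numerical choices

- **Standardization** uses population (1/n) variance, so `crossprod(X)/n`
  is exactly the correlation matrix; genotypes re-standardized after MVN
  sampling keep the marginal-scan algebra exact.
- **LD regularization** is convex shrinkage toward the identity with the
  diagonal kept at 1; for ε > 0 the smallest eigenvalue is at least
  `ε/(1+ε)`, which guarantees the Cholesky factorization and a positive
  TWAS denominator.
- **Degenerate marginal fits** (zero residual variance) are capped at
  `|z| = 1e8` with a warning rather than returning infinities.
- **Monomorphic SNPs** are dropped (with a warning), not errored — small
  fixture panels hit them routinely; missing genotypes are mean-imputed
  before standardization, the standard choice for reference-panel LD.
- **Alignment** between weights, GWAS summaries, and testing LD is by
  SNP identifier with a hard error on mismatch; silent intersection
  would quietly change the statistic.
- **Seeds**: every sampling function takes an explicit seed and restores
  the caller's RNG state; `run_experiment()` derives per-replicate seeds
  from the master seed by a pre-drawn table and records them per row, so
  whole experiments are byte-reproducible.

## The synthetic fixture generator

`fixture_spec()`/`generate_panel()` create diploid panels with
block-exchangeable LD: latent Gaussian haplotypes correlated within
blocks are dichotomized at the allele-frequency threshold and summed in
pairs. This reproduces the qualitative features that matter for the
pipeline — block LD, a realistic MAF spectrum, PLINK round-tripping —
but not fine-scale recombination structure, MAF–LD coupling, or
population stratification. Dichotomization attenuates the realized LD
below the latent `within_block_corr` (a latent 0.8 yields roughly 0.5–0.7
realized), which is accepted and measured rather than corrected.
Passing tests on these fixtures therefore demonstrate statistical
correctness of the pipeline, not realism of any particular locus; runs
on real panels only require a PLINK prefix.

## Experiment designs in the test suite

The checks mirror four standard designs, at problem sizes chosen to keep
the full suite fast on one CPU while leaving Monte-Carlo noise well below
the assertion bands:

- *Null calibration*: 2,000 replicates on a 100-SNP locus (KS test,
  `λ_GC`, nominal rejection); a stricter 20-master-seed joint version
  uses 4,000 replicates per seed so that the fixed `λ_GC ∈ [0.9, 1.1]`
  band sits several Monte-Carlo standard errors from the truth.
- *Power monotonicity* (elastic net): three-point grids in `h2ge`
  (0.0005–0.002), `n_gwas` (10k–40k), and `n_qtl` (100–2,000) at
  `h2g = 0.05`, 200 replicates per cell, spaced so adjacent cells differ
  by far more than binomial noise.
- *LD misspecification*: a 489-sample, 200-SNP strong-LD locus split
  into halves of 244 and 245; the first half simulates GWAS statistics,
  the second drives the eQTL cohort and TWAS testing. GBLUP is used
  here: its dense weights are the most sensitive to LD-metric mismatch,
  and its fits are cheap enough for 500 replicates per arm. Both arms
  share a master seed (common random numbers) so the comparison is
  paired.
- *Linkage pleiotropy*: 50 SNPs in strong 10-SNP blocks, five causal
  eQTLs and five independent direct-effect SNPs, comparing null,
  linkage, and causal runs at matched settings.

## Known limitations

- One locus, one gene per run: no genome-wide background polygenicity
  beyond the cis signal, and no joint multi-gene testing.
- Quantitative traits only; no case–control liability scale, no
  covariates or batch structure in expression.
- Fast mode's mean approximation ignores `O(h2ge)` terms; at `h2ge`
  above ~0.05 standard mode is the safer reference.
- The published full-scale power figures for this class of simulator
  were obtained on 1000 Genomes EUR genotypes; reproducing them requires
  that external panel and is wired into the test suite as an
  opt-in comparison (`options(twasim.1000g_prefix = ...)`).
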