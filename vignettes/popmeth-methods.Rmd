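---
title: "Methods and design of popmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of popmeth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popmeth)
```

`popmeth` analyses two-population molecular cohorts: DNA methylation (EPIC-style
beta values), genotype dosages and RNA-seq expression measured on the same
individuals. This vignette documents the statistical models, the reasoning
behind the tunable parameters, what the synthetic-data generator does and
does not emulate, and the numerical decisions a maintainer would want
written down.

## Scales: beta and M

Methylation is stored as the methylated fraction beta in [0, 1] and analysed
on the M scale, the base-2 logit `M = log2(beta / (1 - beta))`. M has
near-constant variance across the methylation range, which matters for
regression and for variance shrinkage; beta is kept for effect-size
reporting because a "5% methylation difference" is interpretable. Boundary
beta values are clamped to `[1e-6, 1 - 1e-6]` before the logit: the
perturbation is far below measurement precision and keeps M finite. The DMS
effect-size filter deliberately uses *raw* beta group means (not the
covariate-adjusted M coefficient): the two scales answer different
questions — the M-scale model decides significance, the beta difference
decides practical size.

## Differential methylation

Per CpG we fit `M ~ population + age + covariates` by OLS; the covariates
are whatever the study provides (surrogate variables, genotype PCs) and are
consumed as given — surrogate-variable estimation is out of scope. Residual
variances are moderated by empirical Bayes (the limma machinery: log
variances moment-matched to a scaled F distribution, posterior variance
`(d0 s0^2 + df s^2) / (d0 + df)`, moderated t on `df + d0` degrees of
freedom). When all variances are equal the prior degrees of freedom are
infinite and moderation is a no-op — that branch is exercised in the tests,
not an error. A CpG is a differentially methylated site (DMS) when
BH-adjusted p < 0.01 *and* |Δβ| > 0.05; both defaults are the conventional
thresholds for this design and the tests verify planted shifts of
Δβ = 0.1 at n = 78+78 and M-scale noise sd 0.3 are recovered with ≥ 95%
sensitivity.

The sign convention is explicit rather than assumed: `delta_beta` is the
first population minus the second (AFB − EUB under default labels) and
`hyper_in` names the hypermethylated population, so no downstream consumer
needs to guess the orientation.

## QTL and QTM mapping

The cis engine computes, for each feature and each SNP within the window
(100 kb by default; CpG position or gene TSS as anchor):

* a linear additive-model p-value, implemented as the correlation of
  covariate-residualized feature and dosage vectors (algebraically the same
  t-test a matrix-eQTL engine performs, cross-checked against `lm()` per
  pair in the tests), and
* a Kruskal-Wallis rank test across genotype classes. KW cannot absorb
  covariates, so values are residualized on the covariates by OLS before
  ranking; this preserves the nonparametric protection against outliers
  while honouring the covariate set. The same residualization choice is
  applied to the joint-scope Spearman eQTM test (an ancestry indicator is
  regressed out of both variables before ranking), and the output metadata
  records the scope so consumers know the contract.

Significance requires *both* tests to pass their thresholds — robustness
against outlier-driven linear hits and against rank-test quirks at once.
Dropping either test can only grow the discovery set (a monotonicity the
tests assert).

**Permutation FDR.** Sample labels of the molecular matrix are permuted
within each population (genotypes and covariates fixed), the mapping is
re-run (100 permutations by default), and the per-feature minimum p is kept.
`FDR(t)` is the mean permuted count of features with min-p ≤ t over the
observed count; the reported threshold is the largest value of the grid
`{1, 5} x 10^-k, k = 2..12` with `FDR(t) ≤ 0.05`. The grid is made of the
round thresholds practitioners quote; thresholds of 1e-5 (cis) and 1e-9
(trans) are typical outcomes at cohort scale. When no grid point attains
the target the result is an explicit "not attainable" sentinel, never a
silent fallback.

**Stepwise conditioning.** The lead SNP (smallest linear p, ties broken by
larger |effect| then smaller genomic position — a deterministic rule so
re-runs agree) is added to the covariates, the window re-mapped, and the
best remaining SNP promoted while it passes the threshold, up to rank 5.
The cap bounds runtime; in practice independent cis signals beyond rank 5
are vanishingly rare at these sample sizes. Tests verify two unlinked
planted SNPs emerge at ranks 1 and 2 and that an R² = 0.95 proxy of the
causal SNP is absorbed after conditioning.

**trans mapping.** To limit the multiple-testing burden, candidate SNPs are
restricted to variants within 10 kb of an expressed transcription-factor
TSS or detected as cis-eQTLs of those TFs; each candidate is tested (KW on
ancestry-residualized M) against every CpG at least 1 Mb away or on another
chromosome.

## Population genetics

Derived-allele frequencies come from dosages oriented to the derived allele
(generated data records the ancestral state; when unknown the alternate
allele is counted and flagged). Per-SNP FST uses Hudson's two-population
closed form `1 - Hw/Hb` without finite-sample correction, so that
`FST(p, p) = 0` exactly and a fixed difference gives exactly 1; the
estimator is cross-checked against an independent implementation in the
tests.

`ExpDiff = beta * ΔDAF / ΔMeth` expresses the expected allele-frequency-
driven methylation difference as a share of the observed one. It is
deliberately unbounded — opposing environmental or secondary genetic
effects can push it outside [0, 1] — and records with `ΔMeth = 0` are
flagged undefined and excluded from means rather than propagating
infinities.

**Population-specific effects.** Three Gaussian linear models (shared
effect; effect only in one population; only in the other) have identical
parameter counts, so with equal priors the posteriors are the softmax of
the maximized log-likelihoods (profiled error variance; computed in log
space via log-sum-exp to avoid underflow). A *specific* call requires a
posterior above 0.9; "shared" is assigned whenever the shared model merely
tops the ranking, because the 0.9 bar exists to protect the strong claim
(specificity), not the default one.

## Enrichment

Context enrichment compares the query CpGs' category split against the
general distribution of the full background universe (not the complement) —
this is the convention under which a query of 100 CpGs with 50 enhancers on
a background of 1000 with 200 gives OR = 4. Fisher's exact p; Woolf logit
CI with Haldane-Anscombe 0.5 correction for zero cells (flagged).

GWAS enrichment resamples frequency-matched SNP sets: query and background
are LD-pruned greedily (best p per locus at R² < 0.8), the query's pooled
allele-frequency histogram in 5%-wide bins is reproduced exactly in each of
10,000 resamples, and the fold is observed/expected overlap with a
one-sided p from a normal fitted to the resample counts by moments. Pooled
(rather than per-population) frequencies are the neutral matching choice
and are recorded in the design; the bootstrap CI over the query uses an
independent seeded stream so the p-value and CI are not entangled. A query
frequency bin with no background representation is an error naming the bin
— silently dropping bins would bias the match.

## Mediation

For a trio (genetic summary X, methylation summary M, expression Y) the
mediator model `M ~ X + C` and outcome model `Y ~ X + M + C` give the
decomposition `total = ade + acme` with `acme = alpha * beta`. Point
estimates are the OLS products, so the decomposition identity holds to
machine precision on every dataset (the tests assert 1e-8); the
quasi-Bayesian draws — coefficients sampled from their estimated sampling
distributions, ACME as the per-draw product — provide the uncertainty, with
a two-sided p from a normal fit (mean/sd) to the draws. Using the draw mean
as the point estimate instead would trade the exact identity for a hair of
bias correction; we keep the identity. The p is two-sided because the null
`alpha * beta = 0` has no stated direction.

Multi-SNP or multi-CpG trios are collapsed by elastic-net summary variables
(mixing 0.5; 10-fold CV — the conventional k when only "k-fold" is
specified; `lambda.1se` for parsimony, falling back to `lambda.min` with a
warning flag when the 1se rule zeroes every coefficient). Single-predictor
trios use the raw dosage or M value: a penalized fit on one column adds
nothing but shrinkage bias.

The partial-correlation comparator is the first-order partial correlation
of Y and M given X (equivalently the correlation of residuals, asserted to
1e-12 in the tests) with the t transform on n − 3 degrees of freedom.
`benchmark_mediation()` simulates trios per grid cell — half with the
cell's mediated share, half with the mediated share set to zero and the
direct share absorbing it, so the total explained variance is constant
across truth classes — and scores both tests by Mann-Whitney AUC
(identical to trapezoidal ROC AUC). Reverse causation (expression driving
methylation) is not modelled.

## The synthetic-data generator

`simulate_causal_trio()` implements the four-step variance-share
construction exactly: standardize a binomial(2, f) genotype; mix it with
standard-normal noise at share alpha to form M; standardize M; mix M, G and
noise at shares gamma·beta, gamma·tau, 1 − gamma(beta + tau) to form E.
With beta + tau = 1 the expression noise weight is exactly sqrt(1 − gamma),
so gamma = 0.25 leaves 75% of expression variance unexplained — the
quantity the acceptance script recomputes by joint regression at
n = 100,000.

`simulate_cohort()` generates the full two-population dataset: 78 + 78
individuals by default (a balanced two-cohort design); derived-allele
frequencies per population as a shared ancestral frequency plus independent
Normal(0, 0.12) perturbations (a spread that yields realistic ΔDAF values
without fixing many alleles); LD within 1 Mb blocks by copying founder
haplotypes with a per-bp switch probability (default 1e-6, i.e. ~2%
recombination between SNPs 20 kb apart — strong but imperfect local LD);
methylation on the M scale as per-CpG baselines plus planted genetic
effects, beta-scale population shifts (converted to M-scale baseline
offsets), small age and surrogate-variable loadings, and Gaussian noise of
sd 0.3 (0.5 in the noisier meQTL fixtures); expression as log-normal around
per-gene baselines with planted eQTL/eQTM links and noise sd 0.5. M-scale
noise sd 0.3 corresponds to a beta-scale sd of roughly 0.05 at
intermediate methylation — the order observed on real arrays.

What the generator does *not* emulate: EPIC probe chemistry and
detection-p generation (a configurable failure rate only), realistic human
LD maps and recombination hotspots, cell-composition heterogeneity, and
non-linear age effects. Passing recovery tests therefore demonstrate the
*statistical machinery* is correct under the planted model; they do not
certify performance on real arrays where those nuisances exist.

Out-of-range beta values after planting (possible when a shift pushes a
baseline near the boundary) are clamped to (1e-6, 1 − 1e-6) with a warning
— the clamp is recorded rather than silent because it changes the realized
effect size.

## Problem sizes in the test suite

The suite validates calibration on 10,000-feature null panels (raw-p < 0.05
rates asserted in [0.04, 0.06] for the DMS scan, the cis linear test, the
eQTM Spearman test and the ACME p), recovery on 78 + 78 cohorts at the
noise levels above, the mediation closed form on 20 replicates of n = 5000
per grid cell, and the mediation-vs-partial-correlation comparison on 200
replicates of n = 156 per cell over alpha in {0.3, 0.55, 0.8} and beta in
{0.1, 0.5, 0.9} with gamma = 0.25 — sizes chosen so the whole suite runs in
a few minutes while keeping Monte-Carlo error well inside the asserted
tolerances.

## Interface conventions

Every analysis returns a tibble (with `tidy()`/`glance()` and `autoplot()`
methods on the main result types), so pipelines compose with the pipe;
sample-by-feature data lives in plain matrices inside light containers
(`methylation_matrix`, `genotype_matrix`, `expression_matrix`). The package
is function-first by design: the exported functions plus this vignette are
the interface, and file exchange uses plain text — TSV matrices (with an
orientation header comment), BED (0-based half-open, converted from the
1-based positions held in memory), and minimal VCF for genotypes. Strand is
ignored for CpGs, as EPIC-style probes are strand-collapsed. All stochastic
functions take an explicit seed and are bit-reproducible given it.

## Known limitations

* The Spearman p uses the t approximation; for n below ~20 an exact
  permutation p would be preferable.
* The KW chi-square approximation is poor with very unbalanced genotype
  classes near the MAF floor; the dual-test rule mitigates but does not
  remove this.
* The quasi-Bayesian mediation p is a product-of-normals approximation;
  under a complete null (both paths zero) it is conservative, which is why
  calibration is assessed under the realistic null (genetic effect present,
  mediated path absent).
* Elastic-net fold assignment makes summary variables depend on the seed;
  trios near the significance boundary can flip between runs with
  different seeds.
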