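---
title: "Methods: half-sib G-matrix estimation and comparison"
author: "halfsibG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: half-sib G-matrix estimation and comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(halfsibG)
```

## The problem

Whether populations can respond to multivariate selection -- and whether
different populations would respond differently -- is governed by the
additive genetic variance-covariance matrix **G**. `halfsibG` implements the
full workflow for estimating and comparing G matrices from nested paternal
half-sib breeding designs: the classic scheme in which each sire is crossed
to several unique dams, so that the covariance among paternal half-sibs
estimates one quarter of the additive genetic variance (V~A~ = 4 V~S~).

The motivating setting is a common-garden field experiment on an annual
plant measured for six traits (early height, final height, branch number,
flowering date, plus inflorescence length and seed mass as male and female
fitness proxies), with several source populations grown together so that
each population's G can be estimated and the set of G matrices compared.

## The mixed model and its sampler

Each trait vector of individual *l* from dam *k* nested in sire *j* grown in
block *i* follows

$$y_{ijkl} = \mu + B_i + S_j + D_{k(j)} + e_{l(ijk)},$$

with fixed intercept and block effects, random sire effects
$S_j \sim \mathrm{MVN}(0, \Sigma_S)$, dam-within-sire effects
$D_{k(j)} \sim \mathrm{MVN}(0, \Sigma_D)$ and residuals
$e \sim \mathrm{MVN}(0, \Sigma_E)$. The additive genetic covariance matrix
is $G = 4\Sigma_S$.

Estimation is by a Gibbs sampler written in compiled code (`fit_univariate`
for one trait, `fit_multivariate` for several): fixed effects and the random
effects have conjugate multivariate-normal full conditionals, and the three
covariance matrices conjugate inverse-Wishart updates. Priors put the
expectation of the sire and dam covariances at **P**/4 (one quarter of the
observed phenotypic covariance; alternatives **P**/2 and diagonal are
selectable for prior-sensitivity checks) and the residual at **P**/2, with
degree of belief $\nu = n_{\text{traits}} - 0.998$ -- a proper but minimally
informative prior. No parameter expansion is used; chains stuck near zero
would surface through the split-half PSRF screen, which warns (never
silently drops) when any covariance element exceeds a potential scale
reduction factor of 1.2.

The production schedule retains 10,000 draws: 200,000 burn-in (univariate)
or 500,000 (multivariate) followed by 5,000,000 iterations thinned by 500.
The iteration accounting deliberately separates burn-in from post-burn-in
sampling, since 5,000,000/500 = 10,000 is only consistent when the
5,000,000 iterations are all post-burn. All examples, tests and the
analysis drivers use shortened schedules (hundreds to thousands of retained
draws); the conjugate sampler mixes fast enough that lag-1 autocorrelations
of variance components are small at thinning intervals of a few iterations.

Missing trait records default to row-wise complete-case in multivariate
fits (trait-wise in univariate fits); conditional-normal data augmentation
inside the sampler is available via `na_action = "impute"`. Since the
missingness emulated by the generator is completely at random, complete-case
is unbiased and is the faster default.

Traits entering multivariate fits are standardized by their global
(pooled-across-populations) standard deviation (`standardize_traits`); the
SDs are recorded on the table and carried into the fitted object so that
responses to selection can be expressed in trait units or SD units
(`unstandardize_g` undoes the scaling element-wise). "Global" is read as
pooled over all populations; a per-continent reading would change only the
labels, not the machinery.

Heritability is $h^2 = 4V_S/(V_S+V_D+V_E)$, using the within-population
phenotypic variance. Estimates exceed 1 whenever the sire share of variance
exceeds 0.25; they are reported untruncated because truncation would bias
posterior summaries.

## What the generator emulates -- and what it does not

`make_design` + `simulate_phenotypes` + `apply_attrition` generate the
experiment exactly as designed: 6 populations x 50 sires x 3 dams x 3
offspring over 3 blocks (900 families, 2700 transplants) by default, with
multivariate-normal sire/dam/residual effects drawn from a known G, D, E,
additive block offsets, i.i.d. Bernoulli attrition and per-trait
missingness. The default architecture (`default_sim_params`) uses
heritabilities of 0.3, genetic correlations of 0.3, dam covariance D = G/4
(maternal effects of the same order as the sire variance, mirroring the
symmetric prior treatment of sire and dam components), and means/SDs on
scales realistic for an annual weed. Block allocation is a balanced
round-robin within family; the attrition rate of 0.25 in the analysis
drivers reproduces the order of loss seen in field transplant experiments.

Real field data differ in ways the generator deliberately ignores: spatially
structured mortality and microenvironment (attrition here is i.i.d.),
non-normal traits (branch counts, flowering dates), genotype-by-block
interaction, and selection acting before measurement. Passing tests
therefore demonstrate correctness of the machinery under the model's own
assumptions, not robustness to these violations.

## Permutation nulls

Because variance components are constrained positive, their posteriors never
cover zero and classical significance logic fails. The package instead
builds permutation nulls (`permute_within_population`, `build_null`):
phenotype rows are reshuffled within populations -- destroying the
family structure while preserving each trait's multiset exactly -- and every
model is refit on the randomized data (1000 datasets at production scale).
Whole rows move jointly by default, which also preserves the pooled
phenotypic covariance and keeps the multivariate null comparable to the
observed **P**; independent per-trait shuffling is available via
`per_trait = TRUE`. Sub-seeds derive from the master seed by counter, so any
single permutation can be replayed in isolation. Null refits may use
shortened chains (the pipeline scales them 10x down by default) since null
posteriors are summarized only through their means.

HPD intervals are the shortest contiguous interval containing the stated
mass of the empirical sample (sliding-window over the sorted draws).

## Comparison statistics

All five statistics consume per-population posteriors with draws paired by
index, so uncertainty propagates through every derived quantity.

**Krzanowski common subspace.** With $A_t$ holding the first
$k = \lfloor n_{\text{traits}}/2 \rfloor$ unit eigenvectors of population
*t*'s G, the summary matrix $H = \sum_t A_t A_t^T$ has eigenvalues in
$[0, p]$; a value of *p* (the number of populations) marks a direction
common to every population's leading subspace. Six traits give k = 3, four
traits k = 2.

**Covariance tensor.** The fourth-order tensor
$\Sigma_{ijkl} = \mathrm{cov}(G_{ij}, G_{kl})$ is represented as the matrix
**S**: the covariance, across populations, of the G matrices vectorized
over unique elements with off-diagonals weighted by $\sqrt2$ -- the
weighting that makes the Euclidean inner product of vectors equal the
Frobenius inner product of matrices, so eigentensors come out orthonormal.
Eigenvectors of **S** fold back into symmetric eigentensors; the variance
share $\alpha_i$ of each describes how much among-population variation it
captures, its own eigenvectors are the trait combinations responsible
(shares proportional to squared eigenvalues), and population coordinates
(Frobenius inner products with centered G) locate each population on each
axis and sum to zero by construction.

**Breeder's equation.** $\Delta\bar z = G\beta$ per posterior draw. When
$\beta$ is itself a posterior, draws are paired one to one (counts must
match). Responses are computed on unstandardized G (trait units) and also
reported divided by the recorded global SDs.

**R metric.** $R = \beta^TG\beta / \beta^TG_0\beta$, where $G_0$ zeroes
every off-diagonal: the rate of adaptation (change in mean fitness, the
Lande identity -- stated explicitly here as the implemented definition)
with covariances relative to without. R = 1 for any diagonal G; R is
invariant to positive rescaling of $\beta$ or G. Summaries report the mean
and 5th/95th percentiles.

**Random skewers.** Unit-sphere random selection vectors (normalized
standard-normal draws; 1000 by default -- the "large universe" is a
documented choice, since implementations of the method vary) are applied to
each G, and population pairs are compared by the mean vector correlation and
angle of their response vectors, either on posterior means or per draw.

### Numerical conventions

Eigenvector signs follow the largest-|component|-positive rule so results
are reproducible across linear-algebra backends. Eigenvalues are reported
in descending order; exact ties (identical-matrix fixtures) keep the
backend's ordering, which the sign rule makes deterministic in practice.
The per-draw eigenstructure of **S** is summarized on the fixed basis of
the posterior-mean **S**'s eigentensors, avoiding label switching across
draws; the alternative (per-draw decomposition) is rank-ordered and used
for null datasets' own summaries. A tensor with trace below 1e-12 is
reported as "no variation" with all shares zero rather than 0/0.

### Calling divergence against the nulls

Observed and null data pass through *identical* per-draw machinery: each
null dataset's refit posteriors yield the same statistic, summarized by its
posterior mean, and the null HPD band collects these over datasets.
Significance then requires the observed posterior to separate from the null
band -- for Krzanowski, an eigenvalue below *p* whose posterior upper HPD
bound lies below the null band's lower bound (the dual criterion); for the
tensor, a variance share whose posterior lower bound exceeds the null upper
bound. Comparing a point estimate against the null band instead would
mistake estimation noise for divergence: populations sharing one true G
differ in their *estimated* G by sampling noise that the no-structure null
does not reproduce. Breeder's-equation responses and R values are compared
across populations by HPD overlap (response: 95% HPD per trait; R: the
5th-95th band), and skewer correlations against the null by HPD separation.

## Selection gradients

`sire_means` pools sires globally (one regression, so population contrasts
downstream come from G, not from population-specific selection).
`composite_fitness` is PC1 of seed mass and inflorescence length on the
correlation matrix -- the proxies live in incommensurable units (g vs. cm),
so covariance PCA would let the larger-variance proxy dominate -- with the
sign fixed to correlate positively with both. `estimate_beta_point` is the
Lande-Arnold regression of relative fitness on sire-mean traits; fitness is
relativized by its grand mean (standard practice, adopted here as the
default since positive-mean metrics admit it), while a centered composite
index is shifted to a unit-variance relative scale instead -- either way,
rescaling fitness by a positive constant leaves $\beta$ unchanged. Traits
enter on their raw scale (gradients in trait^-1 units), with optional SD
standardization. `estimate_beta_bayes` uses a conjugate Zellner-style
g-prior (g = n, unit information) with a flat intercept and Jeffreys prior
on the residual variance: the posterior is closed-form normal-inverse-gamma,
so the 10,000 default draws are exact rather than a chain, and prior
sensitivity is negligible by construction.

## Problem sizes used by tests and drivers

All sizes are the package's own choices for desk-scale verification.
Parameter-recovery coverage runs 20 replicates of a 200-sire, six-trait
design with 1000 retained draws per fit; the Gibbs-vs-moment-estimator check
uses one balanced 200-sire x 5-dam x 10-offspring fixture; the specificity
experiment runs 3 replicates of 6 populations x 25 sires with 15
permutation datasets each; the analysis drivers run the full 6 x 50 x 3 x 3
design with 40 permutation datasets and 1000 retained draws. The
permutation-calibration test uses the moment estimator as its statistic, so
50+ refits stay cheap.

## Known limitations

* The sampler covers exactly the two-level sire/dam nesting -- no pedigrees
  deeper than half-sib/full-sib, no REML alternative (the balanced-design
  moment estimator `anova_oracle` is a cross-check, not a general
  estimator).
* The P-scaled priors induce upward bias in G at small sire counts (visible
  below ~30 sires); credible-interval coverage is verified at the design's
  own scale (50+ sires).
* Distribution-separation significance calls are conservative: with few
  null datasets or short chains they favour "no divergence", which is the
  right direction for a specificity-first analysis but costs power against
  subtle divergence.
* The MANOVA-style test of mean differences among populations is out of
  scope; standard `manova()` serves there.
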