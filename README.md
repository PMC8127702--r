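# halfsibG

Quantitative-genetic analysis of nested paternal half-sib breeding designs:
simulate field experiments with a known genetic architecture, estimate
additive genetic variance–covariance matrices (**G**) by Gibbs sampling,
build permutation null distributions, and compare G matrices across
populations.

It is written for evolutionary biologists asking whether a set of
populations — for example native and introduced ranges of a colonizing
plant — share the same genetic architecture, and what their G matrices
imply about future responses to selection.

## The model

In a nested paternal half-sib design each sire is crossed to several unique
dams. Traits follow the mixed model

> y<sub>ijkl</sub> = μ + B<sub>i</sub> + S<sub>j</sub> + D<sub>k(j)</sub> + e<sub>l(ijk)</sub>

with fixed block B, random sire S ~ MVN(0, Σ<sub>S</sub>), dam-within-sire
D ~ MVN(0, Σ<sub>D</sub>) and residual e ~ MVN(0, Σ<sub>E</sub>). The
covariance of paternal half-sibs estimates V<sub>A</sub>/4, so
**G** = 4 Σ<sub>S</sub> and h² = 4 V<sub>S</sub> / (V<sub>S</sub> +
V<sub>D</sub> + V<sub>E</sub>). Estimation is by conjugate Gibbs sampling
(inverse-Wishart priors with expectation **P**/4 and degree of belief
ν = n<sub>traits</sub> − 0.998) in compiled code; significance comes from
permutation nulls (phenotypes reshuffled within populations, models refit).

Comparisons across populations:

* **Krzanowski common subspace** — H = Σ<sub>t</sub> A<sub>t</sub>A<sub>t</sub><sup>T</sup>;
  eigenvalues of H reach the number of populations for shared leading
  subspaces.
* **Genetic covariance tensor** — eigentensors of
  Σ<sub>ijkl</sub> = cov(G<sub>ij</sub>, G<sub>kl</sub>) with variance
  shares α and the trait combinations driving divergence.
* **Breeder's equation** — Δz̄ = **G**β per posterior draw, β from
  Lande–Arnold regressions on sire means (point or exact Bayesian
  posterior).
* **R metric** — β<sup>T</sup>**G**β / β<sup>T</sup>**G₀**β (off-diagonals
  zeroed): do covariances accelerate (R > 1) or constrain (R < 1)
  adaptation?
* **Random skewers** — vector correlations of responses to random unit
  selection vectors.

## Worked example

Simulate a small two-population experiment from a known architecture, fit G
for one population, and compare populations:

```r
library(halfsibG)

pars <- default_sim_params(h2 = 0.3, r_g = 0.3, seed = 7)
design <- make_design(n_populations = 2, n_sires = 30, n_dams_per_sire = 3,
                      n_offspring_per_dam = 3, n_blocks = 3)
tab <- simulate_phenotypes(design, pars)
std <- standardize_traits(tab)

cfg <- mcmc_config(burn_in = 500, post_burn_iterations = 2000, thin = 2,
                   seed = 3)
g <- fit_multivariate(std, "P1", cfg)
g
#> G-matrix posterior for population P1
#>   6 traits, 1000 retained draws, 270 individuals / 30 sires
#>   standardization: global SD units
#> posterior mean G:
#>                      early_height final_height branch_number flowering_date
#> early_height               0.7423       0.2003        0.0927         0.2662
#> final_height               0.2003       0.7972        0.2707         0.2032
#> ...
```

The posterior mean G is reported in global-SD units (the generative G had
h² = 0.3 with correlations 0.3; at 30 sires the P/4-scaled prior pulls
small-sample estimates upward — coverage is verified at the design's full
50+ sire scale). Comparing identical architectures yields the no-divergence
geometry:

```r
Gs <- list(P1 = g, P2 = fit_multivariate(std, "P2", cfg))
round(krzanowski_subspace(Gs)$eig_mean, 3)
#> [1] 1.990 1.913 1.540 0.460 0.087 0.010
round(r_metric(g, c(0.2, -0.1, 0.15, 0.05, 0, 0))$mean, 3)
#> [1] 0.956
```

The leading H eigenvalues sit near the bound p = 2, as they must when both
populations are draws from one shared G; the R metric near 1 says this G's
covariances neither accelerate nor constrain adaptation under that
(discordant-sign) gradient.

## The analysis workflow

The `analysis/` drivers run the full study at desk scale and narrate what
they find, writing tables under `results/`:

1. `01_simulate.R` — 6 populations × 50 sires × 3 dams × 3 offspring
   (2700 transplants) with 25% field attrition.
2. `02_fit_gmatrices.R` — per-population heritabilities and G posteriors.
3. `03_permutation_nulls.R` — 40 randomized datasets, null h² and null G.
4. `04_compare_gmatrices.R` — Krzanowski, tensor and skewers vs. the nulls.
5. `05_selection_response.R` — composite fitness, β, predicted responses,
   R metric.

`run_pipeline(pipeline_config(...))` performs the same stages
programmatically with a single master seed and byte-reproducible outputs.
The methods vignette (`vignettes/halfsib-gmatrix-methods.Rmd`) documents the
model, priors, null construction and all numerical conventions.

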