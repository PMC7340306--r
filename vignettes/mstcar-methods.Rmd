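---
title: "Bayesian space-time small-area estimation of death rates: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian space-time small-area estimation of death rates: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mstcar)
```

## The problem

County-level death rates for specific causes and demographic groups are
notoriously unstable: many counties contribute only a handful of deaths per
year, and some have group populations of a few dozen people. Crude rates
`deaths / population` in such cells are dominated by Poisson noise, and
year-over-year trend estimates computed from them are close to meaningless.
The standard remedy in disease mapping is hierarchical Bayesian smoothing:
each county borrows strength from its neighbours on the map, from adjacent
years, and from correlated demographic groups, producing stabilized rate
estimates with honest uncertainty.

This package implements that full pipeline: a multivariate space-time
conditional autoregressive (MSTCAR) model fitted by Markov chain Monte
Carlo, followed by direct age-standardization, reliability-based
suppression, and log-linear trend estimation carried out on the posterior
samples. A generative simulator produces synthetic county mortality data
with known parameters, which is how every stage of the pipeline is
validated.

## The model

Let `Y_ikt` be the death count in county `i`, demographic group `k`, and
year `t`, with person-years at risk `n_ikt`. The likelihood is Poisson,

```
Y_ikt ~ Poisson(n_ikt * lambda_ikt)
ln(lambda_ikt) ~ Normal(beta_kt + Z_ikt, tau_k^2)
```

where `beta_kt` is a free group-by-year intercept with a vague `N(0, 100)`
prior, `tau_k^2` is a group-level lognormal cell variance whose precision
carries a weakly informative `Gamma(0.001, 0.001)` prior, and `Z_ikt` is
the structured spatiotemporal random effect.

`Z` follows a multivariate space-time CAR law with a separable
(Kronecker-product) precision:

* **Space**: the intrinsic (Besag-style) CAR over the county adjacency
  graph, precision `Q = D - W` where `W` is the 0/1 adjacency matrix and
  `D` the diagonal of neighbour counts. `Q` is rank-deficient — its null
  space is spanned by the indicators of the graph's connected components —
  so propriety is restored by a sum-to-zero constraint on `Z` within every
  component for every `(k, t)`.
* **Time**: a stationary AR(1) process with coefficient `rho` in `(0, 1)`
  and unit marginal variance, `Beta(1, 1)` prior on `rho`. The first year
  is drawn from the stationary distribution.
* **Groups**: an unstructured covariance matrix `G` (K x K) with an
  inverse-Wishart prior, default `IW(K + 2, 0.1 * I)`.

Writing `P(rho)` for the tridiagonal AR(1) precision, the prior precision
of the matricized `Z` is `P(rho) ⊗ G^{-1} ⊗ Q` on the constrained
subspace. A shared `rho` across groups is used; this is a modelling choice
(a group-specific AR coefficient is a natural extension but adds K - 1
weakly identified parameters at the county scale the package targets).

### Interpretation of the hyperparameters

| parameter | role | default | units |
|---|---|---|---|
| `beta_prior_var` | vagueness of intercept prior | 100 | log-rate² |
| `tau2_shape`, `tau2_rate` | prior on `1/tau_k²` | 0.001, 0.001 | — |
| `iw_df`, `iw_scale` | prior on `G` | `K + 2`, `0.1 I` | — |
| `rho_a`, `rho_b` | Beta prior on `rho` | 1, 1 | — |

The gamma and inverse-Wishart defaults are deliberately weak: with even a
modest county map the data supply thousands of effective replicates for
`tau_k^2` and `G`, so the prior matters only in near-degenerate cases.

## The sampler

The model is fitted by Metropolis-within-Gibbs with a fixed, documented
block order: `log_lambda → beta → Z → tau2 → G → rho`. The order is a
determinism/testability decision; any fixed order targets the same
posterior.

* **`log_lambda`** has no conjugate update (Poisson-lognormal), so each
  cell uses random-walk Metropolis on its full conditional. Proposal
  scales are per-cell, `proposal_sd / sqrt(Y + 1/tau² + 0.5)` — an
  approximation to the conditional standard deviation, so acceptance is
  roughly uniform across cells whose counts span five orders of magnitude —
  times a per-group factor adapted toward the scalar-target acceptance
  rate 0.44 during burn-in and frozen afterwards, so the post-burn-in
  chain satisfies detailed balance exactly. Cells with `n = 0` have no
  likelihood and are drawn exactly from the prior normal; they are kept so
  array shapes (and downstream standardization) are stable.
* **`beta`, `tau2`, `G`** are conjugate draws (normal, gamma on the
  precision, inverse-Wishart). The inverse-Wishart degrees of freedom
  increment is `T * rank(Q)` = `T * (N - c)` with `c` the number of
  connected components — the effective number of replicates of the
  between-group covariance under the constrained Kronecker prior.
* **`Z`** uses block Gibbs by county: conditional on its neighbours, a
  county's `K*T` effect vector is Gaussian with precision
  `m_i * (P ⊗ G^{-1}) + I_T ⊗ diag(1/tau²)`. Counties are grouped by graph
  colour (greedy colouring; same-colour counties are mutually non-adjacent
  and hence conditionally independent) and by neighbour count `m`, which
  indexes a shared Cholesky factor, so the whole sweep is a handful of
  small factorizations plus batched triangular solves. The sum-to-zero
  constraint is re-imposed per component and `(k, t)` after every sweep;
  the free intercept `beta_kt` absorbs the level.
* **`rho`** uses random-walk Metropolis on `(0, 1)`; proposals outside the
  support are rejected. The target combines the Beta prior with the
  AR(1) profile of `Z`: `K(N - c)(T - 1)/2 * -log(1 - rho²)` from the
  normalizing determinant plus the tridiagonal quadratic form.

Chains run sequentially, each from a seed derived from the root seed, with
initial values at smoothed empirical log-rates `ln((Y + 0.5)/(n + 1))`
jittered across chains. Runs are bit-reproducible for a fixed
configuration and invariant to the order in which units or rows are
presented (unit ids are sorted internally).

### Numerical choices

* Log-rate proposals outside `[-30, 5]` are rejected rather than clamped:
  rejection truncates the target support (a harmless restriction — rates
  outside `e^-30` to `e^5` per person-year are not meaningful) while
  value-clamping would break proposal symmetry. Rejections at the floor
  are counted and reported in `glance()`.
* Inverse-Wishart draws that fail the Cholesky (possible only in
  near-singular corners) are retried with a jittered scale, with a
  warning.
* Defaults follow common practice for this model class — 4 chains of 6000
  iterations, 3000 burn-in. The thinning default is 3 (1000 stored draws
  per chain), a storage/precision compromise; it is configurable.
* Posterior summaries are medians with equal-tailed 95% intervals from the
  2.5/97.5 percentiles, computed with linear-interpolation quantiles
  (type 7).
* Convergence is monitored with split-chain potential-scale-reduction
  statistics on the intercepts, variances, `rho`, and a sample of rate
  cells; values above 1.1 are flagged. With a single chain the two halves
  of that chain are compared (with a warning) — a weaker, within-chain
  check.

## The synthetic-data generator

`make_scenario()` draws data from exactly the model above: `Z` from the
constrained MSTCAR law via the spectral decomposition of `Q` (only
positive-eigenvalue directions carry variance, which enforces the
component-wise sum-to-zero constraint by construction), then cell
log-rates with `tau` noise, then Poisson counts. County populations are
log-uniform between 50 and 500,000 — mimicking the heavy right skew of
real county populations — with a configurable fraction of units forced
near or below the 100-person threshold so the suppression rules are
exercised. The `"national"` preset is shaped like a national analysis:
a 15 x 15 county lattice (225 units), six demographic groups (two genders
by three ten-year age bands), and 39 annual observations (1979–2017), with
group-specific levels, a gentle secular decline that flattens late in the
period, `rho = 0.9`, `tau² = 0.01` and a between-group covariance with
unit correlations of 0.5 at scale 0.05.

What the generator does *not* emulate: cause-of-death coding and its
misclassification, demographic covariates beyond group labels, population
migration (populations drift only ±10% around their base), irregular
county geographies (the preset lattice is rook-adjacency; arbitrary
symmetric neighbour lists are supported but not auto-derived from
geometry), and non-stationary or non-separable space-time interaction.
Passing tests on these scenarios therefore demonstrates correctness of
the *estimation machinery* under the model's own assumptions, not
robustness to the many ways real vital-statistics data violate them.

## Post-processing

**Age-standardization** is direct: standardized rate = `Σ_a w_a λ_a` with
weights from the 2000 US standard million (10-year bands), renormalized
over the bands present in the model (an analysis restricted to ages 45+
uses the 45+ bands of the standard renormalized to 1). Standardization is
linear and is applied to *draws*, never to summaries, so margins (e.g.
both genders combined) and intervals inherit full posterior uncertainty.
Rates are reported per 100,000 person-years.

**Suppression** applies two rules at the (county, group) level across the
whole period, so the same county set is used in every year: a series is
suppressed if any year's 95% credible-interval width is not smaller than
its point estimate (reliability), or if any year's population is 100
people or fewer (strictly greater than 100 is required). The any-year
reading of the reliability rule is the conservative resolution of an
ambiguity (any-year vs all-year); it guarantees every reported series is
reliable everywhere. Suppressed rows are retained but masked in outputs.

**Trends** are estimated by ordinary least squares of log rate on calendar
year — separately for each posterior draw's time series — over four
default intervals (1979–1990, 1990–2000, 2000–2010, 2010–2017; adjacent
intervals deliberately share their boundary year, matching the printed
labels). The annual percent change is `100 (e^slope - 1)`; total change
over an interval is compounded at the draw level,
`100 (e^{slope * span} - 1)`, then summarized. A county is classified
*increasing* when its median APC is positive; the posterior probability of
a positive slope is reported alongside so stricter rules can be applied.
The share of counties increasing is itself given posterior uncertainty by
computing the fraction of positive-slope counties *within each draw* and
summarizing across draws — the natural Bayesian construction for the
interval on that statistic.

## Validation strategy and problem sizes

The test suite validates each stage against an independent oracle:

* a single-county model against 2-D numerical quadrature of the exact
  posterior (agreement of posterior mean and variance of the log-rate
  within 2%);
* every Gibbs block against its closed-form full conditional
  (Kolmogorov–Smirnov, alpha 0.01, Bonferroni across blocks, 10,000
  draws);
* parameter recovery on ten replicate 10 x 10-county, two-group, ten-year
  simulations (95% intervals cover the generating intercepts in at least
  90% of cells and `rho`/`tau²` in at least 8 of 10 replicates);
* the shrinkage direction on a 150-person county embedded among large
  high-rate neighbours (posterior median strictly between crude rate and
  neighbour mean in at least 95% of 20 replicates);
* trend analytics on noise-free exponential series (exact to machine
  precision) and the standardization/suppression identities on
  constructed cases;
* the full pipeline on the 225-county, six-group, 39-year preset with
  reduced chains (2 x 1000 iterations), checking that the
  percent-of-counties-increasing statistic covers the generator's ground
  truth within its posterior interval.

These sizes are the package's own validation choices: large enough that
Monte-Carlo error is far below the tolerances, small enough that the whole
suite runs on a laptop in minutes.

## Known limitations

* The intrinsic CAR has no spatial-dependence parameter to estimate;
  alternatives (proper CAR, Leroux) are out of scope.
* The space-time interaction is separable; a non-separable MSTCAR variant
  would need different full conditionals.
* No covariates enter the mean structure; `beta_kt` is saturated in
  group-by-year.
* Metropolis on tens of thousands of `log_lambda` cells mixes slowly for
  cells with enormous counts; the adaptive per-cell scales mitigate but do
  not remove this.
* Model comparison (DIC/WAIC) and choropleth mapping are intentionally
  not provided.
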