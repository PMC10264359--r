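---
title: "Hurdle joint species distribution models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hurdle joint species distribution models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`hjsdm` fits a hierarchical Bayesian joint species distribution model to
haul-by-species count matrices from standardized bottom-trawl surveys.
Because such counts are strongly zero-inflated, the model is a hurdle: two
sub-models are fitted independently to the same design.

* **PA** (presence-absence): a multivariate probit. With latent
  $z_{ij} = x_i^\top \beta_j + \eta_i^\top \lambda_j + \varepsilon_{ij}$,
  $\varepsilon_{ij} \sim N(0,1)$, a species is present when $z_{ij} > 0$.
* **ABU** (abundance conditional on presence): a Gaussian linear model on
  species-scaled log counts. Within each species $j$, $\log y_{ij}$ over its
  presence hauls is standardized to mean 0 and unit variance (sample sd,
  $n-1$); the scaling constants $(m_j, s_j)$ are retained for
  back-transforming predictions. Scaling keeps every species compatible with
  shared default priors.

The covariates are the intercept, natural-log depth, bottom temperature,
a sand/mud seabed contrast (mud to muddy sand is the reference level),
natural-log swept area (the effort offset-like covariate) and a centered
linear year term. Species niches $\beta_j$ are pooled across species through
traits and phylogeny:

$$
B \sim \mathcal{MN}\!\left(\Gamma^\top T^\top,\; V,\; \rho C + (1-\rho) I\right),
$$

where $T$ holds the species traits (intercept, age at first maturity,
viviparous/oviparous, trophic level), $\Gamma$ the trait-to-niche effects,
$V$ the residual covariance of niches across covariates, and $C$ a species
correlation derived from the ranked taxonomy (one unit-length edge per rank;
the correlation between two species is the fraction of the six root-to-tip
edges they share). The mixing weight $\rho \in [0,1]$ is the phylogenetic
signal: 0 means trait-adjusted niches are independent across species, 1
means they are fully structured by the taxonomy.

Residual co-occurrence is modelled by two latent-factor random levels:

* **spatial** (haul level): factors follow a zero-mean, unit-variance
  Gaussian process over haul positions with exponential covariance
  $\exp(-d/\alpha)$, distances in km from a local equirectangular
  projection; the range $\alpha$ is sampled on a discrete grid that includes
  0 (no spatial structure);
* **temporal** (year level): i.i.d. unit-variance factors per survey year.

Factor loadings carry the multiplicative-gamma shrinkage prior, so
unneeded factors collapse towards zero. The factor count per level is fixed
(default 3) rather than adaptively truncated, which keeps the posterior
dimension constant across draws.

## Inference

A blocked Gibbs sampler updates, per sweep: the latent probit responses
(exact one-sided truncated normals, computed through the survival function
so deep tails stay accurate); the pair $(B, \Gamma)$ in one exact joint
multivariate-normal draw (dimension $K(p+q)$, built from Kronecker
products); $V$ (conjugate inverse-Wishart, prior scale $I$, df $K+1$);
$\rho$ (discrete draw on its grid, default 101 uniform points, using the
eigenbasis of $C$ so the scan is $O(Gp)$); the factor fields
(per-factor conditional draws in a precomputed eigenbasis of the kernel,
one basis per candidate range); the loadings (joint across levels, species
by species); the shrinkage hyperparameters; and, for ABU, the residual
standard deviations (conjugate inverse-gamma, prior shape 1, rate 1).
$\Gamma$ has a $N(0, 100)$ prior per element.

Two design choices deserve note:

* **Missing conditional abundances.** ABU responses exist only at
  presences. The sampler imputes the missing entries from their conditional
  $N(L_{ij}, \sigma_j^2)$ each sweep. This augmentation is exact (the
  marginal posterior is the row-subset posterior) and keeps the conditional
  precision of every spatial-factor update in the form $K^{-1} + cI$, which
  a fixed eigendecomposition diagonalizes; row-subsetting instead would make
  the precision site-heterogeneous and force an $O(n^3)$ factorization per
  sweep.
* **Spatial-range refresh interval.** Evaluating the GP likelihood of a
  factor at a candidate range costs one $O(n^2)$ basis rotation per
  candidate. The range move is therefore run every 5th sweep by default
  (`alpha_every`); any fixed scan order remains a valid Gibbs sampler, and
  the range is the slowest-varying quantity in the model.

With more than 2000 hauls the spatial level switches automatically to a
predictive (inducing-point) Gaussian process on a regular knot grid
(default 64 knots); at or below that size the full covariance is used. The
published-scale protocol (4 chains x 37,500 iterations, burn-in 12,500,
thinning 100) is available through `mcmc_control()`; the default desk-scale
protocol is 2 chains x 3,000 (burn-in 1,000, thinning 10), which the
recovery experiments below show is sufficient for the synthetic study
conditions. One master seed drives everything; per-chain and per-sub-model
streams are derived deterministically, so a fit is bit-for-bit
reproducible.

## What the synthetic generator emulates

The restricted survey data are emulated by `hjsdm_scenario()` /
`simulate_community()`, which generate from exactly the model the sampler
assumes, with known ground truth: nine elasmobranch species with the
published trait table and taxonomy; ~coastal-basin geometry (a 12.2-18 E,
41.9-45.8 N box); log-uniform depths on 10-270 m; bottom temperature as a
depth-driven lapse plus a smooth spatial field, clamped to 7-27 C; a binary
seabed class from a thresholded smooth field; swept areas lognormal with
median 0.047 km^2; years 1996-2019 assigned round-robin. Defaults plant a
negative viviparity-by-depth trait effect and phylogenetic signal
$\rho = 0.85$ in both sub-models, echoing the qualitative findings the
model family is used for. Because log-depth enters uncentered, the planted
viviparity intercept (+4.55) offsets the viviparity depth slope (-1.2) at
the mean log depth; the net effect is depth segregation by reproductive
mode at roughly equal overall prevalence. Default residual niche variances
were chosen so that species prevalences span roughly 1-35% ("sporadic to
common", matching the survey's 2.6-25.8% span) while keeping at least a
handful of presences per species at the default 1,500 hauls.

What the generator does **not** emulate: gear selectivity and
catchability, seasonal redistribution, overdispersion beyond the lognormal
(counts are rounded expected abundances with a floor of 1 at presences),
spatially structured sampling designs (hauls are uniform in the box), or
model misspecification of any kind. Passing recovery tests therefore
demonstrates the correctness and calibration of the inference machinery
under the assumed data-generating process, not robustness to the
mismatches real survey data would add.

## Downstream products

* **Diagnostics.** Split-chain PSRF (each chain halved; the conservative
  modern variant); Tjur $R^2$ and Mann-Whitney AUC for PA; ABU $R^2$ as the
  squared Pearson correlation between posterior-mean prediction and
  observation over presences (the variance-explained alternative was
  rejected for its dependence on calibration of the predictive variance).
  All metrics are explanatory (in-sample), computed from posterior-mean
  draw-wise predictions.
* **Variance partitioning.** Computed per draw and species — the fixed
  groups as the variance over hauls of each group's contribution, each
  random level as its loading sum of squares (the factors have unit
  marginal variance) — then fractions are averaged over draws and
  renormalized. The constant intercept carries no variance.
* **Trait share of niche variation.** Per covariate and draw, the
  across-species variance of the trait prediction $\Gamma^\top T^\top$
  divided by that of $B$, clipped to $[0,1]$; the single overall number
  averages the per-covariate shares weighted by each covariate's mean share
  of explained variance. The weighting is a package decision (the source
  analyses report single numbers without a formula); it is configurable by
  using the per-covariate output directly.
* **Prediction.** Occurrence probability, conditional abundance and their
  per-draw product (expected abundance) on a grid, with swept area fixed at
  the survey standard 0.047 km^2, the target year's temporal factor, and
  spatial factors interpolated by the GP conditional mean given each draw's
  field (deterministic per draw; no re-simulation noise in maps). The
  conditional abundance is back-transformed with the lognormal mean
  correction $\exp(m_j + s_j\mu + \tfrac12 s_j^2\sigma_j^2)$ by default —
  expected abundance is the stated target — with plain exponentiation
  available (`correction = FALSE`).
* **Abundance indices.** Expected abundance per standardized haul is
  divided by the standard swept area to give a density, integrated over
  cell areas ($0.05^\circ$ cells: $(0.05 \cdot 111.32)^2\cos(\mathrm{lat})$
  km^2), summed over cells, and scaled so the baseline-year posterior mean
  is 1. The density interpretation of "raising abundance to the cell area"
  is a package decision; indices are invariant to any constant rescaling of
  abundance either way.
* **Community-weighted mean traits.** Abundance-weighted trait means per
  cell and draw (age at maturity, viviparous fraction, trophic level);
  the annual community trend aggregates cells by abundance weighting
  (an unweighted cell mean is the obvious alternative; weighting was chosen
  so the trend reflects where the community actually is), with the
  posterior probability of decline reported.

## Numerical choices and degenerate inputs

Natural logarithms throughout (the convention of the HMSC framework (hierarchical modelling of species communities) this package follows); year is
centered at the mean survey year for numerical stability. Covariance
matrices are verified positive semi-definite with tolerance $10^{-8}$ on
the smallest eigenvalue; conditional precisions that fail Cholesky get a
$10^{-8}$ relative jitter with a warning. The GP kernel carries a
$10^{-6}$ diagonal jitter so duplicate haul positions are allowed. Species
with fewer than two presence hauls (scaling undefined) or constant positive
counts are rejected with instructions to filter more strictly; rank-deficient
designs are rejected naming the most collinear columns. Degenerate
zero-variance limits ($V = 0$, $s_j = 0$) are handled exactly rather than
by jitter. All-presence or all-absence species yield `NA` discrimination
metrics; fewer than three presences yield `NA` ABU $R^2$.

## Problem sizes used in the shipped experiments

The test suite exercises the full pipeline at sizes a desk machine handles
comfortably: parameter recovery on the default 1,500-haul scenario at the
desk-scale MCMC protocol; sampler calibration by simulation-based
calibration (128 replicates of a 12-haul, 3-species model with one spatial
and one temporal factor, 30 retained draws each, rank-uniformity of 20
statistics); oracle checks of every closed-form quantity on fixtures of at
most 10 rows. The packaged example survey has 120 hauls. These sizes are
the package's reference experiment design; all of them scale up through
`hjsdm_scenario()` and `mcmc_control()` without code changes.

## Known limitations

PA and ABU are fitted independently (as in the HMSC hurdle
usage); the hurdle does not share latent fields across sub-models, and no
zero-inflated single-likelihood alternative is provided. Explanatory, not
predictive, power is reported — there is no cross-validation machinery.
The taxonomy-based correlation is a coarse surrogate for a dated
phylogeny; with nine species the posterior of $\rho$ is informative but
wide. For sporadic species the ABU sub-model sees only a few dozen
presence hauls over a restricted environmental range, so individual
coefficients — especially the intercept, an extrapolation to 1 m depth on
the uncentered log-depth scale — are weakly identified and shrink towards
their trait prediction even when the in-range linear predictor is
recovered well; summaries that pool raw coefficients across species
inherit this volatility. The predictive-process approximation underestimates marginal
variances slightly away from knots; variance partitioning treats all
factors as unit-variance regardless. Abundance indices assume the swept
area standard converts haul expectations to densities homogeneously across
the domain.
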