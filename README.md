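# hjsdm — hurdle joint species distribution models for trawl-survey counts

`hjsdm` is for ecologists analysing multi-species count data from
standardized bottom-trawl surveys — the motivating case is a nine-species
demersal elasmobranch community sampled by ~4,000 hauls over two decades in
a shallow, heavily exploited basin. Such data are zero-inflated, spatially
and temporally structured, and per-species too sparse to model species one
at a time. The package fits a hierarchical Bayesian joint species
distribution model (JSDM) with a hurdle:

* **PA**: multivariate probit for presence-absence,
  `P(y_ij > 0) = Φ(x_iᵀβ_j + η_iᵀλ_j)`;
* **ABU**: Gaussian regression on species-scaled log abundance conditional
  on presence (per species, log counts at presences standardized to mean 0,
  sd 1).

Species niches are pooled through traits and phylogeny,

```
B ~ MN( Γᵀ Tᵀ ,  V ,  ρC + (1 − ρ)I )
```

with `T` the trait matrix (age at first maturity, reproductive mode,
trophic level, plus intercept), `Γ` the trait→niche effects, `V` the
residual niche covariance and `C` a taxonomy-derived species correlation;
`ρ ∈ [0,1]` is the phylogenetic signal. Residual co-occurrence is captured
by spatially (Gaussian-process, exponential kernel) and temporally
structured latent factors. Everything is sampled by a blocked Gibbs
sampler; downstream products are variance partitioning, trait and
phylogenetic-signal summaries, Tjur R²/AUC/R² diagnostics, split-chain
PSRF, gridded prediction of occurrence and expected abundance, annual
abundance indices and community-weighted mean (CWM) traits.

Because the motivating survey data are access-restricted, the package
ships a first-class synthetic survey generator (`hjsdm_scenario()`,
`simulate_community()`) that produces data with exactly the assumed
structure and known ground truth, so the whole pipeline is testable end to
end.

## Worked example

```r
library(hjsdm)

sc  <- hjsdm_scenario(n_hauls = 1500, seed = 101)   # default study conditions
sim <- simulate_community(sc)

fit <- hjsdm(sim$community,
             traits   = adriatic_traits(),
             taxonomy = adriatic_taxonomy(),
             mcmc     = mcmc_control(seed = 11))    # 2 x 3000, burn-in 1000
print(fit)
```

```
Hurdle joint species distribution model (probit PA + Gaussian ABU)
  1500 hauls, 9 species, 6 covariates, years 1996-2019
  2 chains x 3000 iterations (burn-in 1000, thin 10): 400 draws
  phylogenetic signal E[rho]: PA 0.91 (Pr>0 1.00), ABU 0.92 (Pr>0 1.00)
```

The generator planted `ρ = 0.85` in both sub-models, so posterior means
near 0.9 with `Pr[ρ>0] = 1` are the model recovering a strong phylogenetic
signal. Recovery of the planted niches and of the planted negative
viviparity-by-depth trait effect:

```r
cor(as.vector(coef(fit, "pa")), as.vector(sim$truth$B_pa))
#> [1] 0.98
gs <- gamma_support(fit, "pa")
gs[gs$trait == "repro_mode" & gs$covariate == "log_depth", ]
#>        trait covariate  mean pr_positive sign
#> 7 repro_mode log_depth -1.15       0.005    -
```

The posterior-mean β correlates with truth at 0.98, and the viviparity
effect on depth is recovered near its planted value (−1.2) with 99.5%
posterior support for the negative sign — viviparous species prefer
shallower water in these data by construction. Explanatory power and
variance shares:

```r
summary(fit)
#> Explanatory power (community means):
#>   Tjur R2 0.355 | AUC 0.941 | ABU R2 0.599
#> Phylogenetic signal:
#>   PA: E[rho] = 0.91, Pr[rho > 0] = 1.00
#>   ABU: E[rho] = 0.92, Pr[rho > 0] = 1.00
#> Mean variance shares:
#>   PA: depth 59%, temperature 2%, seabed 1%, effort 1%, year 5%,
#>       random_spatial 27%, random_temporal 6%
#>   ABU: depth 53%, temperature 9%, seabed 4%, effort 2%, year 6%,
#>       random_spatial 20%, random_temporal 7%
#> Convergence (max split-chain PSRF by block):
#>   ABU: 1.228
#>   PA: 1.225
```

Tjur R² is the mean predicted occurrence probability at presences minus
that at absences; AUC near 0.94 says presences are ranked above absences
almost always. Prediction products on a grid:

```r
grid <- read_grid("my_grid.csv")           # cell_id, lon, lat, covariates
p    <- predict(fit, grid, type = "occurrence")   # cells x species x draws
maps <- richness_and_any(p)                       # richness, P(any species)
idx  <- abundance_index(fit, grid, baseline_year = 1996)
cwm  <- cwm_trend(fit, grid)                      # community trait trends
```

`abundance_index()` scales each species' area-integrated expected
abundance so the baseline-year posterior mean is 1 and reports the
posterior probability of the end-of-series change; `cwm_trend()` reports
the posterior probability that community-weighted age at maturity,
viviparous fraction and trophic level declined.

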