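#' MCMC configuration for [hjsdm()]
#'
#' The published-scale protocol (4 chains of 37,500 iterations, 12,500
#' burn-in, thinning 100) is available by setting those values; the default
#' is a desk-scale protocol of 2 chains x 3,000 iterations, 1,000 burn-in,
#' thinning 10 (400 retained draws).
#'
#' @param n_chains number of chains, each with its own derived seed.
#' @param n_iter iterations per chain.
#' @param n_burnin burn-in iterations discarded (must be `< n_iter`).
#' @param thin thinning interval (>= 1).
#' @param seed master seed; chain streams are derived deterministically.
#' @param rho_grid support of the discrete phylogenetic-signal prior; must
#'   include 0 and 1 (default: 101 equispaced points on `[0, 1]`).
#' @param rho_prior prior weights over `rho_grid` (default uniform).
#' @param n_factors_max latent factors per random level (fixed, no adaptive
#'   truncation).
#' @param gp_mode `"auto"` (full GP covariance up to 2000 hauls, then
#'   predictive process), `"full"`, or `"predictive"`.
#' @param n_knots knots of the predictive Gaussian process (regular grid
#'   over the sampled domain; >= 4).
#' @param alpha_grid candidate spatial ranges in km (first entry 0 = no
#'   spatial structure); `NULL` chooses a grid from the domain extent.
#' @param alpha_prior prior weights over `alpha_grid` (default uniform).
#' @param alpha_every refresh interval (in sweeps) of the spatial-range move,
#'   the one update whose cost scales with the candidate count.
#' @param shrink multiplicative-gamma shrinkage hyperparameters for the
#'   factor loadings (`nu`, `a1`, `b1`, `a2`, `b2`).
#' @param gamma_var prior variance of the trait effects Gamma.
#' @param V_scale,V_df inverse-Wishart prior on the residual niche
#'   covariance V (defaults: identity scale, `n_covariates + 1` df).
#' @param sigma_prior `c(shape, rate)` of the inverse-gamma prior on the ABU
#'   residual variances.
#' @param fixed optional list pinning `V`, `rho`, `sigma` or `Gamma` at known
#'   values (used in validation tests).
#' @return a validated list of class `hjsdm_control`.
#' @export
mcmc_control <- function(n_chains = 2, n_iter = 3000, n_burnin = 1000,
                         thin = 10, seed = 1,
                         rho_grid = seq(0, 1, length.out = 101),
                         rho_prior = NULL,
                         n_factors_max = 3,
                         gp_mode = c("auto", "full", "predictive"),
                         n_knots = 64,
                         alpha_grid = NULL, alpha_prior = NULL,
                         alpha_every = 5,
                         shrink = list(nu = 3, a1 = 50, b1 = 1, a2 = 50, b2 = 1),
                         gamma_var = 100,
                         V_scale = NULL, V_df = NULL,
                         sigma_prior = c(1, 1),
                         fixed = list()) {
  gp_mode <- match.arg(gp_mode)
  if (n_burnin >= n_iter) stop("n_burnin must be smaller than n_iter")
  if (thin < 1) stop("thin must be >= 1")
  if (!(0 %in% rho_grid) || !(1 %in% rho_grid))
    stop("rho_grid must include 0 and 1")
  if (is.unsorted(rho_grid)) stop("rho_grid must be ordered")
  if (is.null(rho_prior)) rho_prior <- rep(1 / length(rho_grid), length(rho_grid))
  if (length(rho_prior) != length(rho_grid))
    stop("rho_prior must match rho_grid")
  structure(list(n_chains = n_chains, n_iter = n_iter, n_burnin = n_burnin,
                 thin = thin, seed = seed, rho_grid = rho_grid,
                 rho_prior = rho_prior, n_factors_max = n_factors_max,
                 gp_mode = gp_mode, n_knots = n_knots,
                 alpha_grid = alpha_grid, alpha_prior = alpha_prior,
                 alpha_every = alpha_every, shrink = shrink,
                 gamma_var = gamma_var, V_scale = V_scale, V_df = V_df,
                 sigma_prior = sigma_prior, fixed = fixed),
            class = "hjsdm_control")
}

# default candidate ranges: none, plus four log-spaced fractions of the
# domain extent
.default_alpha_grid <- function(coords_km) {
  dmax <- sqrt(sum((apply(coords_km, 2, max) - apply(coords_km, 2, min))^2))
  c(0, dmax * c(0.05, 0.1, 0.2, 0.35))
}

#' Fit the hurdle joint species distribution model
#'
#' Fits the presence-absence (probit) and conditional-abundance (Gaussian on
#' species-scaled log abundance) sub-models independently by blocked Gibbs
#' sampling. Both share the fixed-effect design of [build_design()], the
#' trait regression, the taxonomy- or tree-derived phylogenetic correlation
#' and two latent-factor random levels: haul-level spatial factors (unit
#' variance Gaussian process, exponential kernel, range drawn on a grid) and
#' year-level temporal factors (i.i.d. unit variance). Conditional-abundance
#' entries at absences are unobserved and are integrated out by exact
#' augmentation.
#'
#' @param community a community table (see [validate_community()]), already
#'   species-filtered (see [filter_species()]).
#' @param traits trait table as from [read_traits()]; rows must cover all
#'   species columns of `community`.
#' @param taxonomy ranked taxonomy (see [read_taxonomy()]); used to build the
#'   phylogenetic correlation when `phylo` is absent.
#' @param phylo optional tree (`ape::phylo`, Newick path or string); takes
#'   precedence over `taxonomy`.
#' @param mcmc an [mcmc_control()].
#' @param verbose print progress.
#' @return an object of class `hjsdm` with components `pa` and `abu`
#'   (posterior draws), `design`, `hurdle`, `traits`, `C`, `species`,
#'   `coords_km`, `years`, and a reproducibility `manifest` (call, seed,
#'   configuration).
#' @export
hjsdm <- function(community, traits, taxonomy = NULL, phylo = NULL,
                  mcmc = mcmc_control(), verbose = FALSE) {
  validate_community(community)
  stopifnot(inherits(mcmc, "hjsdm_control"))
  design <- build_design(community)
  hur <- make_hurdle(community)
  species <- colnames(hur$Y_pa)
  if (!all(species %in% traits$species))
    stop("traits missing for species: ",
         paste(setdiff(species, traits$species), collapse = ", "))
  traits <- traits[match(species, traits$species), ]
  Tm <- .trait_design(traits)
  C <- if (!is.null(phylo)) {
    phylo_correlation(phylo, species = species)
  } else if (!is.null(taxonomy)) {
    taxonomy_to_correlation(taxonomy)[species, species]
  } else {
    diag(1, length(species))
  }

  centre <- c(mean(community$lon), mean(community$lat))
  coords <- project_km(community$lon, community$lat, centre = centre)
  years <- sort(unique(community$year))
  mode <- switch(mcmc$gp_mode,
                 auto = if (nrow(coords) <= 2000) "full" else "predictive",
                 mcmc$gp_mode)
  alpha_grid <- if (is.null(mcmc$alpha_grid)) .default_alpha_grid(coords)
                else mcmc$alpha_grid
  levels_struct <- list()
  if (mcmc$n_factors_max > 0) {
    sp_st <- .spatial_struct(coords, alpha_grid, mode = mode,
                             n_knots = mcmc$n_knots,
                             alpha_prior = mcmc$alpha_prior)
    sp_st$name <- "spatial"; sp_st$k_factors <- mcmc$n_factors_max
    tm_st <- .temporal_struct(match(community$year, years), length(years))
    tm_st$name <- "temporal"; tm_st$k_factors <- mcmc$n_factors_max
    levels_struct <- list(spatial = sp_st, temporal = tm_st)
  }
  K <- ncol(design$X)
  ctrl <- mcmc
  if (is.null(ctrl$V_scale)) ctrl$V_scale <- diag(K)
  if (is.null(ctrl$V_df)) ctrl$V_df <- K + 1

  if (verbose) message("fitting PA (probit) sub-model")
  pa <- .gibbs_sampler(hur$Y_pa, "probit", design$X, Tm, C, levels_struct,
                       ctrl, seed_offset = 0L, verbose = verbose)
  if (verbose) message("fitting ABU (Gaussian) sub-model")
  abu <- .gibbs_sampler(hur$Y_abu, "gaussian", design$X, Tm, C, levels_struct,
                        ctrl, seed_offset = 104729L, verbose = verbose)

  structure(list(pa = pa, abu = abu,
                 design = design, hurdle = hur, traits = traits, C = C,
                 species = species, centre = centre, coords_km = coords,
                 years = years, year_mean = design$year_mean,
                 community = community,
                 manifest = list(call = match.call(), seed = mcmc$seed,
                                 control = ctrl, gp_mode = mode,
                                 alpha_grid = alpha_grid,
                                 fitted_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                                 r_version = R.version.string)),
            class = "hjsdm")
}
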