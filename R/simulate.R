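#' Local equirectangular projection to kilometres
#'
#' Projects WGS84 decimal degrees about a reference point (default: the
#' centroid) so Euclidean distances approximate great-circle km; adequate at
#' the basin scales (hundreds of km) modelled here.
#'
#' @param lon,lat coordinates in decimal degrees.
#' @param centre optional `c(lon0, lat0)` reference point.
#' @return two-column matrix `x`, `y` in km.
#' @export
project_km <- function(lon, lat, centre = NULL) {
  if (is.null(centre)) centre <- c(mean(lon), mean(lat))
  kpd <- 111.32  # km per degree latitude
  cbind(x = (lon - centre[1]) * kpd * cos(centre[2] * pi / 180),
        y = (lat - centre[2]) * kpd)
}

# trait design T' (species x {intercept, traits}); raw trait scales
.trait_design <- function(traits) {
  Tm <- cbind(intercept = 1,
              age_maturity = traits$age_maturity,
              repro_mode = traits$repro_mode,
              trophic_level = traits$trophic_level)
  rownames(Tm) <- traits$species
  Tm
}

.covariate_names <- c("intercept", "log_depth", "bot_temp", "seabed_sand",
                      "log_swept_area", "year_centered")

#' Define a synthetic survey scenario
#'
#' Bundles every generative parameter of the synthetic bottom-trawl survey:
#' the sampling frame (haul count, years, bounding box emulating a shallow
#' semi-enclosed basin), species traits and taxonomy, the trait-to-niche
#' regression `Gamma`, residual niche covariance `V`, phylogenetic signal
#' `rho`, spatial/temporal latent factor loadings `Lambda` with spatial range
#' `alpha_km`, conditional-abundance residual sd `sigma`, and per-species log
#' count location/scale `(m, s)` used to map scaled log abundance to counts.
#'
#' Defaults emulate the study conditions of the Adriatic elasmobranch
#' analysis: nine species with the published trait table and taxonomy, depth
#' 10-270 m, bottom temperature within 7-27 deg C, swept area with median
#' 0.047 km^2, years 1996-2019, prevalences spanning sporadic to common, a
#' planted negative viviparity-by-depth trait effect and `rho = 0.85`.
#'
#' @param n_hauls number of hauls (default 1500, the desk-scale frame).
#' @param years survey years, assigned round-robin.
#' @param bbox named numeric `c(lon_min, lon_max, lat_min, lat_max)`.
#' @param traits,taxonomy species tables (defaults: packaged Adriatic ones).
#' @param gamma_pa,gamma_abu trait (incl. intercept) x covariate matrices.
#' @param V_pa,V_abu covariate-residual covariances of the niches.
#' @param rho_pa,rho_abu phylogenetic signal weights in `[0, 1]`.
#' @param n_factors named integer `c(spatial =, temporal =)` latent factors.
#' @param alpha_km spatial range (km) of the exponential GP kernel.
#' @param lambda_pa,lambda_abu lists with `spatial` and `temporal` loading
#'   matrices (factor x species).
#' @param sigma_abu per-species residual sd of scaled log abundance.
#' @param m,s per-species log-count location and scale.
#' @param seed mandatory integer seed.
#' @return object of class `hjsdm_scenario` (a validated list).
#' @export
hjsdm_scenario <- function(n_hauls = 1500,
                           years = 1996:2019,
                           bbox = c(lon_min = 12.2, lon_max = 18.0,
                                    lat_min = 41.9, lat_max = 45.8),
                           traits = adriatic_traits(),
                           taxonomy = adriatic_taxonomy(),
                           gamma_pa = NULL, gamma_abu = NULL,
                           V_pa = NULL, V_abu = NULL,
                           rho_pa = 0.85, rho_abu = 0.85,
                           n_factors = c(spatial = 2, temporal = 1),
                           alpha_km = 40,
                           lambda_pa = NULL, lambda_abu = NULL,
                           sigma_abu = NULL,
                           m = NULL, s = NULL,
                           seed) {
  if (missing(seed)) stop("a seed is mandatory in a scenario")
  p <- nrow(traits)
  sp <- traits$species
  block <- rep(c(1, -1), length.out = p)            # default two-block loadings
  half <- rep(c(1, 1, -1), length.out = p)
  if (is.null(gamma_pa))
    gamma_pa <- rbind(intercept     = c(1.50, -0.80, 0.02, 0.20, 0.50, 0.010),
                      age_maturity  = c(-0.03, 0, 0, 0, 0, 0),
                      repro_mode    = c(4.55, -1.20, 0.03, 0, 0, 0),
                      trophic_level = c(0, 0, 0, 0, 0, 0))
  if (is.null(gamma_abu))
    gamma_abu <- rbind(intercept     = c(1.80, -0.45, 0.01, 0.10, 0.30, 0.005),
                       age_maturity  = c(0, 0, 0, 0, 0, 0),
                       repro_mode    = c(1.95, -0.50, 0.02, 0, 0, 0),
                       trophic_level = c(0, 0, 0, 0, 0, 0))
  colnames(gamma_pa) <- colnames(gamma_abu) <- .covariate_names
  if (is.null(V_pa))  V_pa  <- diag(c(0.09, 0.01, 4e-4, 0.09, 0.01, 4e-4))
  if (is.null(V_abu)) V_abu <- diag(c(0.04, 0.01, 4e-4, 0.04, 2.5e-3, 1e-4))
  dimnames(V_pa) <- dimnames(V_abu) <- list(.covariate_names, .covariate_names)
  if (is.null(lambda_pa))
    lambda_pa <- list(spatial  = rbind(0.9 * block, 0.5 * half)[seq_len(n_factors[["spatial"]]), , drop = FALSE],
                      temporal = rbind(0.4 * block)[seq_len(n_factors[["temporal"]]), , drop = FALSE])
  if (is.null(lambda_abu))
    lambda_abu <- list(spatial  = rbind(0.6 * block, 0.3 * half)[seq_len(n_factors[["spatial"]]), , drop = FALSE],
                       temporal = rbind(0.3 * block)[seq_len(n_factors[["temporal"]]), , drop = FALSE])
  if (is.null(sigma_abu)) sigma_abu <- rep(0.6, p)
  if (is.null(m)) m <- seq(2.5, 1.0, length.out = p)
  if (is.null(s)) s <- rep(0.9, p)
  names(sigma_abu) <- names(m) <- names(s) <- sp

  sc <- structure(list(n_hauls = n_hauls, years = years, bbox = bbox,
                       traits = traits, taxonomy = taxonomy,
                       gamma_pa = gamma_pa, gamma_abu = gamma_abu,
                       V_pa = V_pa, V_abu = V_abu,
                       rho_pa = rho_pa, rho_abu = rho_abu,
                       n_factors = n_factors, alpha_km = alpha_km,
                       lambda_pa = lambda_pa, lambda_abu = lambda_abu,
                       sigma_abu = sigma_abu, m = m, s = s, seed = seed),
                  class = "hjsdm_scenario")
  .validate_scenario(sc)
  sc
}

.validate_scenario <- function(sc) {
  stopifnot(sc$n_hauls >= 1, length(sc$years) >= 1)
  if (sc$bbox[["lon_max"]] <= sc$bbox[["lon_min"]] ||
      sc$bbox[["lat_max"]] <= sc$bbox[["lat_min"]])
    stop("degenerate bounding box (zero extent)")
  if (sc$rho_pa < 0 || sc$rho_pa > 1 || sc$rho_abu < 0 || sc$rho_abu > 1)
    stop("rho must lie in [0, 1]")
  if (sc$alpha_km <= 0) stop("spatial range alpha_km must be positive")
  .check_psd(sc$V_pa, "V_pa"); .check_psd(sc$V_abu, "V_abu")
  invisible(sc)
}

#' Draw haul locations and environmental covariates
#'
#' Depth is log-uniform on 10-270 m; bottom temperature is a depth-driven
#' lapse plus a smooth spatial field and noise, clamped to 7-27 deg C; the
#' binary seabed class thresholds a smooth spatial field (sand vs mud to
#' muddy sand); swept area is a narrow lognormal with median 0.047 km^2;
#' coordinates are uniform in the box and years are assigned round-robin.
#'
#' @param scenario a [hjsdm_scenario()].
#' @param seed optional seed; when `NULL` the current RNG stream is used.
#' @return `data.frame` of haul covariates (no count columns yet).
#' @export
draw_environment <- function(scenario, seed = NULL) {
  .validate_scenario(scenario)
  if (!is.null(seed)) set.seed(seed)
  n <- scenario$n_hauls
  b <- scenario$bbox
  lon <- stats::runif(n, b[["lon_min"]], b[["lon_max"]])
  lat <- stats::runif(n, b[["lat_min"]], b[["lat_max"]])
  xy <- project_km(lon, lat, centre = c(mean(b[1:2]), mean(b[3:4])))
  depth <- exp(stats::runif(n, log(10), log(270)))
  temp <- 26 - 3.6 * log(depth / 10) +
    1.6 * sin(xy[, "x"] / 90) * cos(xy[, "y"] / 70) + stats::rnorm(n, 0, 0.8)
  temp <- pmin(27, pmax(7, temp))
  sand_field <- sin(xy[, "x"] / 60) + cos(xy[, "y"] / 45) + stats::rnorm(n, 0, 0.6)
  seabed <- ifelse(sand_field > 0, "sand", "mud_to_muddy_sand")
  swept <- stats::rlnorm(n, log(0.047), 0.25)
  data.frame(haul_id = sprintf("h%05d", seq_len(n)),
             lon = lon, lat = lat,
             year = rep_len(scenario$years, n),
             depth = depth, bot_temp = temp, seabed = seabed,
             swept_area = swept, stringsAsFactors = FALSE)
}

#' Draw species niches from the trait/phylogeny prior
#'
#' `B` (covariate x species) is matrix-normal with mean `t(Gamma) %*% t(T')`,
#' row covariance `V` and column covariance `rho C + (1 - rho) I`, where `C`
#' is the taxonomy-derived correlation. With `rho = 0` niches are
#' independent across species given their traits.
#'
#' @inheritParams draw_environment
#' @param submodel `"pa"` or `"abu"`.
#' @return covariate x species matrix of niches.
#' @export
draw_species_parameters <- function(scenario, submodel = c("pa", "abu"),
                                    seed = NULL) {
  submodel <- match.arg(submodel)
  .validate_scenario(scenario)
  if (!is.null(seed)) set.seed(seed)
  G <- scenario[[paste0("gamma_", submodel)]]
  V <- scenario[[paste0("V_", submodel)]]
  rho <- scenario[[paste0("rho_", submodel)]]
  Tm <- .trait_design(scenario$traits)
  C <- taxonomy_to_correlation(scenario$taxonomy)[scenario$traits$species,
                                                  scenario$traits$species]
  .check_psd(C, "C")
  Sig <- rho * C + (1 - rho) * diag(nrow(C))
  M <- t(G) %*% t(Tm)                           # covariate x species
  K <- nrow(M); p <- ncol(M)
  Z <- matrix(stats::rnorm(K * p), K, p)
  cV <- .chol_psd(V); cS <- .chol_psd(Sig)
  B <- M + t(cV) %*% Z %*% cS
  dimnames(B) <- list(.covariate_names, scenario$traits$species)
  B
}

# upper-triangular Cholesky tolerant of PSD (zero-variance) matrices; the
# all-zero matrix is its own factor so degenerate limits are exact
.chol_psd <- function(A, jitter = 1e-10) {
  if (all(A == 0)) return(A)
  tryCatch(chol(A), error = function(e) chol(A + jitter * mean(diag(A) + 1) * diag(nrow(A))))
}

#' Draw spatio-temporal latent fields
#'
#' Each spatial factor is a zero-mean unit-variance Gaussian process over
#' haul locations with exponential covariance `exp(-d / alpha)` (d in km via
#' [project_km()]; 1e-6 diagonal jitter so duplicate coordinates are
#' allowed); temporal factors are i.i.d. standard normal per year.
#'
#' @inheritParams draw_environment
#' @param lon,lat haul coordinates.
#' @param years vector of distinct years.
#' @param n_factors named `c(spatial =, temporal =)` counts.
#' @param alpha_km spatial range in km.
#' @return list with `eta_spatial` (haul x factor) and `eta_temporal`
#'   (year x factor, rownames = years).
#' @export
draw_latent_fields <- function(scenario = NULL, lon, lat, years,
                               n_factors = scenario$n_factors,
                               alpha_km = scenario$alpha_km, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (alpha_km <= 0) stop("alpha_km must be positive")
  n <- length(lon)
  ks <- n_factors[["spatial"]]; kt <- n_factors[["temporal"]]
  eta_s <- matrix(0, n, ks)
  if (ks > 0) {
    d <- as.matrix(stats::dist(project_km(lon, lat)))
    Kmat <- exp(-d / alpha_km) + diag(1e-6, n)
    cK <- chol(Kmat)
    eta_s <- t(cK) %*% matrix(stats::rnorm(n * ks), n, ks)
  }
  eta_t <- matrix(stats::rnorm(length(years) * kt), length(years), kt,
                  dimnames = list(as.character(years), NULL))
  list(eta_spatial = eta_s, eta_temporal = eta_t)
}

#' Simulate a full synthetic community survey
#'
#' Assembles the hurdle generative model: for each sub-model the linear
#' predictor is `L = X B + eta Lambda` (independent niches, loadings and
#' fields for PA and ABU); presence is `1[L_pa + eps > 0]` with standard
#' normal `eps`; where present, scaled log abundance is `L_abu + e`,
#' `e ~ N(0, sigma_j^2)`, and the recorded count is
#' `max(1, round(exp(m_j + s_j v)))`. Returns the community table alongside
#' the full ground-truth bundle for recovery testing.
#'
#' @param scenario a [hjsdm_scenario()]; `scenario$seed` seeds everything.
#' @return object of class `hjsdm_sim`: list with `community` (a valid
#'   community table) and `truth` (all generative parameters and fields).
#' @export
simulate_community <- function(scenario) {
  .validate_scenario(scenario)
  set.seed(scenario$seed)
  env <- draw_environment(scenario)
  X <- .design_matrix_from_covariates(env)
  sp <- scenario$traits$species
  p <- length(sp); n <- nrow(env)
  yr_idx <- match(env$year, scenario$years)
  out <- list()
  for (sub in c("pa", "abu")) {
    B <- draw_species_parameters(scenario, sub)
    fl <- draw_latent_fields(scenario, env$lon, env$lat, scenario$years)
    lam <- scenario[[paste0("lambda_", sub)]]
    L <- X %*% B
    if (nrow(lam$spatial)) L <- L + fl$eta_spatial %*% lam$spatial
    if (nrow(lam$temporal)) L <- L + fl$eta_temporal[yr_idx, , drop = FALSE] %*% lam$temporal
    out[[sub]] <- list(B = B, fields = fl, L = L)
  }
  pres <- (out$pa$L + matrix(stats::rnorm(n * p), n, p)) > 0
  v <- out$abu$L + matrix(stats::rnorm(n * p), n, p) %*% diag(scenario$sigma_abu, p)
  counts <- ifelse(pres,
                   pmax(1, round(exp(sweep(sweep(v, 2, scenario$s, "*"),
                                           2, scenario$m, "+")))),
                   0)
  colnames(counts) <- paste0("sp_", sp)
  community <- cbind(env, as.data.frame(counts))
  validate_community(community)
  truth <- list(scenario = scenario, X = X,
                B_pa = out$pa$B, B_abu = out$abu$B,
                fields_pa = out$pa$fields, fields_abu = out$abu$fields,
                L_pa = out$pa$L, L_abu = out$abu$L,
                presence = pres, v_abu = v)
  structure(list(community = community, truth = truth), class = "hjsdm_sim")
}

# design matrix from a covariate frame (no count columns required)
.design_matrix_from_covariates <- function(df) {
  cbind(intercept      = rep(1, nrow(df)),
        log_depth      = log(df$depth),
        bot_temp       = df$bot_temp,
        seabed_sand    = as.numeric(as.character(df$seabed) == "sand"),
        log_swept_area = log(df$swept_area),
        year_centered  = df$year - mean(df$year))
}
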