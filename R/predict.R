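#' Areas of grid cells in km^2
#'
#' For a regular longitude-latitude grid of the given resolution, the cell
#' area is `(res * 111.32) * (res * 111.32 * cos(lat))` km^2.
#'
#' @param lat cell-centre latitudes in degrees.
#' @param resolution cell size in degrees (default 0.05).
#' @return numeric vector of areas.
#' @export
cell_areas <- function(lat, resolution = 0.05) {
  (resolution * 111.32)^2 * cos(lat * pi / 180)
}

# GP conditional-mean interpolation of the spatial factors to new sites, per
# draw, using each draw's range alpha: eta_tilde = K_*n K_nn^{-1} eta (full
# mode) or K_*m K_mm^{-1} eta_knots (predictive mode). alpha = 0 gives 0.
.interp_spatial <- function(object, lev, coords_new, jitter = 1e-6) {
  if (is.null(lev) || lev$k_factors == 0) return(NULL)
  n_new <- nrow(coords_new)
  k <- lev$k_factors
  nd <- dim(lev$eta)[3]
  out <- array(0, c(n_new, k, nd))
  alphas <- lev$alpha                               # k x draws
  for (a in setdiff(unique(as.vector(alphas)), 0)) {
    if (lev$mode == "predictive") {
      kn <- lev$knots
      Kmm <- exp(-as.matrix(stats::dist(kn)) / a) + diag(jitter, nrow(kn))
      A <- exp(-.cross_dist(coords_new, kn) / a) %*% chol2inv(chol(Kmm))
      src <- lev$eta_knots
    } else {
      co <- object$coords_km
      Knn <- exp(-as.matrix(stats::dist(co)) / a) + diag(jitter, nrow(co))
      A <- exp(-.cross_dist(coords_new, co) / a) %*% chol2inv(chol(Knn))
      src <- lev$eta
    }
    for (h in seq_len(k)) {
      dd <- which(alphas[h, ] == a)
      if (length(dd))
        out[, h, dd] <- A %*% src[, h, dd]
    }
  }
  out
}

# design matrix for a prediction grid: swept area standardized, year as
# given, bottom temperature per cell (survey-period mean)
.grid_design <- function(object, grid, year, swept_area) {
  df <- data.frame(depth = grid$depth, bot_temp = grid$bot_temp,
                   seabed = grid$seabed, swept_area = swept_area,
                   year = year)
  X <- .design_matrix_from_covariates(df)
  X[, "year_centered"] <- year - object$year_mean
  fitX <- object$design$X
  for (cn in c("log_depth", "bot_temp")) {
    rg <- range(fitX[, cn])
    if (any(X[, cn] < rg[1] - 1e-9 | X[, cn] > rg[2] + 1e-9))
      warning("grid covariate '", cn, "' outside the fitted range; ",
              "predictions extrapolate")
  }
  X
}

#' Posterior prediction on a grid
#'
#' Predicts, per grid cell, species and posterior draw: the occurrence
#' probability `Phi(X B + eta Lambda)` from the PA sub-model
#' (`type = "occurrence"`), the abundance conditional on presence
#' back-transformed to the count scale (`type = "conditional"`), or their
#' product, the expected abundance per standardized haul
#' (`type = "expected"`). Spatial factors are interpolated to cell centres
#' by the GP conditional mean given each draw's posterior field; the
#' temporal factor of the target year is used. Swept area is fixed at the
#' survey standard (0.047 km^2 by default).
#'
#' The conditional abundance applies the lognormal mean back-transform
#' `exp(m_j + s_j mu + 0.5 s_j^2 sigma_j^2)`; set `correction = FALSE` for
#' plain exponentiation of the latent mean.
#'
#' @param object an `hjsdm` fit.
#' @param newdata prediction grid (see [read_grid()]): `cell_id`, `lon`,
#'   `lat`, `depth`, `bot_temp`, `seabed` (and optionally `cell_area`).
#' @param year target year (default: last fitted year).
#' @param type `"occurrence"`, `"conditional"` or `"expected"`.
#' @param swept_area standardized swept area in km^2.
#' @param correction apply the lognormal half-variance correction.
#' @param ... unused.
#' @return array cell x species x draw.
#' @export
predict.hjsdm <- function(object, newdata, year = max(object$years),
                          type = c("expected", "occurrence", "conditional"),
                          swept_area = 0.047, correction = TRUE, ...) {
  type <- match.arg(type)
  X <- .grid_design(object, newdata, year, swept_area)
  coords_new <- project_km(newdata$lon, newdata$lat, centre = object$centre)
  parts <- list()
  need <- c(occurrence = type %in% c("occurrence", "expected"),
            conditional = type %in% c("conditional", "expected"))
  if (need[["occurrence"]])
    parts$p <- .predict_linear(object, "pa", X, coords_new, year,
                               transform = stats::pnorm)
  if (need[["conditional"]]) {
    mu <- .predict_linear(object, "abu", X, coords_new, year,
                          transform = identity)
    parts$cond <- .back_transform(object, mu, correction)
  }
  out <- switch(type, occurrence = parts$p, conditional = parts$cond,
                expected = parts$p * parts$cond)
  dimnames(out) <- list(as.character(newdata$cell_id), object$species, NULL)
  out
}

# linear predictor per draw on new sites (optionally transformed); the
# temporal factor uses the target year's fitted level
.predict_linear <- function(object, submodel, X, coords_new, year, transform,
                            eta_sp = NULL) {
  post <- object[[submodel]]
  nd <- post$n_draws
  n_new <- nrow(X)
  p <- length(object$species)
  if (is.null(eta_sp) && "spatial" %in% names(post$levels))
    eta_sp <- .interp_spatial(object, post$levels$spatial, coords_new)
  yr_idx <- match(year, object$years)
  out <- array(NA_real_, c(n_new, p, nd))
  for (d in seq_len(nd)) {
    L <- X %*% post$B[, , d]
    if (!is.null(eta_sp)) {
      k <- post$levels$spatial$k_factors
      if (k > 0) {
        Lam <- matrix(post$levels$spatial$Lambda[, , d], nrow = k)
        L <- L + matrix(eta_sp[, , d], ncol = k) %*% Lam
      }
    }
    if ("temporal" %in% names(post$levels) && !is.na(yr_idx)) {
      kt <- post$levels$temporal$k_factors
      if (kt > 0) {
        Lam_t <- matrix(post$levels$temporal$Lambda[, , d], nrow = kt)
        eta_t <- matrix(post$levels$temporal$eta[yr_idx, , d], nrow = 1)
        L <- L + matrix(rep(eta_t %*% Lam_t, each = n_new), n_new, p)
      }
    }
    out[, , d] <- transform(L)
  }
  out
}

# scaled log-abundance draws -> conditional abundance on the count scale
.back_transform <- function(object, mu, correction) {
  sp <- object$hurdle$scale_params
  nd <- dim(mu)[3]
  out <- mu
  for (d in seq_len(nd)) {
    m <- sweep(sweep(matrix(mu[, , d], dim(mu)[1]), 2, sp$s, "*"), 2, sp$m, "+")
    if (correction) {
      sig <- object$abu$sigma[, d]
      m <- sweep(m, 2, 0.5 * sp$s^2 * sig^2, "+")
    }
    out[, , d] <- exp(m)
  }
  out
}

#' Species richness and probability of any species
#'
#' Per cell and posterior draw: expected richness `sum_j p_j` and the
#' probability of encountering at least one species
#' `1 - prod_j (1 - p_j)`.
#'
#' @param p array cell x species x draw of occurrence probabilities.
#' @return list with matrices `richness` and `pr_any` (cell x draw) and a
#'   `summary` data.frame of posterior means and sds per cell.
#' @export
richness_and_any <- function(p) {
  richness <- apply(p, c(1, 3), sum)
  pr_any <- 1 - apply(1 - p, c(1, 3), prod)
  list(richness = richness, pr_any = pr_any,
       summary = data.frame(cell = seq_len(nrow(richness)),
                            richness_mean = rowMeans(richness),
                            richness_sd = apply(richness, 1, stats::sd),
                            pr_any_mean = rowMeans(pr_any),
                            pr_any_sd = apply(pr_any, 1, stats::sd)))
}

#' Expected abundance as the hurdle product
#'
#' Elementwise (per draw) product of occurrence probability and conditional
#' abundance.
#'
#' @param p,conditional arrays cell x species x draw.
#' @return array of the same shape.
#' @export
expected_abundance <- function(p, conditional) {
  stopifnot(all(dim(p) == dim(conditional)))
  p * conditional
}

#' Annual abundance indices from gridded predictions
#'
#' Converts per-haul expected abundance to density (dividing by the
#' standardized swept area), integrates it over the cell areas, and sums
#' across cells, per species, year and posterior draw. Indices are scaled so
#' the baseline year's posterior mean equals 1, and the trend probability is
#' the posterior probability that the last year exceeds (or falls below,
#' whichever direction the posterior mean indicates) the first.
#'
#' @param object an `hjsdm` fit.
#' @param grid prediction grid with `cell_area` (see [read_grid()]).
#' @param years years to index (default: all fitted years).
#' @param baseline_year scaling year (default: first of `years`).
#' @param swept_area standardized swept area (km^2).
#' @param correction lognormal back-transform correction, see
#'   [predict.hjsdm()].
#' @return list with `index` (year x species x draw array), `summary`
#'   (posterior mean and 50%/95% intervals, long format) and `trend`
#'   (per species: direction and probability).
#' @export
abundance_index <- function(object, grid, years = object$years,
                            baseline_year = min(years), swept_area = 0.047,
                            correction = TRUE) {
  stopifnot(baseline_year %in% years)
  if (is.null(grid$cell_area)) stop("grid must carry cell_area (km^2)")
  coords_new <- project_km(grid$lon, grid$lat, centre = object$centre)
  eta_pa <- .interp_spatial(object, object$pa$levels$spatial, coords_new)
  eta_abu <- .interp_spatial(object, object$abu$levels$spatial, coords_new)
  nd <- object$pa$n_draws
  p <- length(object$species)
  totals <- array(NA_real_, c(length(years), p, nd),
                  dimnames = list(as.character(years), object$species, NULL))
  wts <- grid$cell_area / swept_area
  for (yi in seq_along(years)) {
    X <- .grid_design(object, grid, years[yi], swept_area)
    pr <- .predict_linear(object, "pa", X, coords_new, years[yi],
                          stats::pnorm, eta_sp = eta_pa)
    mu <- .predict_linear(object, "abu", X, coords_new, years[yi],
                          identity, eta_sp = eta_abu)
    a <- pr * .back_transform(object, mu, correction)
    for (d in seq_len(nd))
      totals[yi, , d] <- colSums(a[, , d] * wts)
  }
  base_mean <- apply(totals[as.character(baseline_year), , , drop = FALSE],
                     2, mean)
  if (any(base_mean == 0)) stop("baseline-year total abundance is zero")
  index <- sweep(totals, 2, base_mean, "/")
  qs <- apply(index, c(1, 2), stats::quantile,
              probs = c(0.025, 0.25, 0.5, 0.75, 0.975))
  summary <- data.frame(
    year = rep(years, times = p),
    species = rep(object$species, each = length(years)),
    mean = as.vector(apply(index, c(1, 2), mean)),
    q025 = as.vector(qs[1, , ]), q25 = as.vector(qs[2, , ]),
    q50 = as.vector(qs[3, , ]), q75 = as.vector(qs[4, , ]),
    q975 = as.vector(qs[5, , ]))
  first <- index[1, , , drop = FALSE]; last <- index[length(years), , , drop = FALSE]
  mean_up <- apply(last, 2, mean) > apply(first, 2, mean)
  pr_trend <- vapply(seq_len(p), function(j) {
    if (mean_up[j]) mean(last[1, j, ] > first[1, j, ])
    else mean(last[1, j, ] < first[1, j, ])
  }, 0)
  list(index = index, summary = summary,
       trend = data.frame(species = object$species,
                          direction = ifelse(mean_up, "increase", "decrease"),
                          pr = pr_trend))
}

#' Community-weighted mean traits
#'
#' Per cell and draw, the abundance-weighted mean of each trait:
#' `CWM_i = sum_j a_ij t_j / sum_j a_ij` for age at first maturity, the
#' viviparous fraction (mean of the binary reproductive mode) and trophic
#' level. Cells with zero total abundance get `NA`.
#'
#' @param a array cell x species x draw of (expected) abundances.
#' @param traits trait table covering the species dimension, in order.
#' @return list of cell x draw matrices: `age_maturity`, `viviparous`,
#'   `trophic_level`.
#' @export
cwm_traits <- function(a, traits) {
  stopifnot(dim(a)[2] == nrow(traits))
  tot <- apply(a, c(1, 3), sum)
  one <- function(tv) {
    num <- apply(sweep(a, 2, tv, "*"), c(1, 3), sum)
    out <- num / tot
    out[tot == 0] <- NA_real_
    out
  }
  list(age_maturity = one(traits$age_maturity),
       viviparous = one(traits$repro_mode),
       trophic_level = one(traits$trophic_level))
}

#' Annual community trend of CWM traits
#'
#' For each year, predicts expected abundance over the grid, computes the
#' community-weighted mean traits per cell and draw, aggregates them across
#' cells by abundance weighting, and reports the posterior probability that
#' the last year's community value lies below the first year's.
#'
#' @inheritParams abundance_index
#' @return list with `cwm` (year x trait x draw array), `summary` (long
#'   format posterior mean and 50/95% intervals) and `pr_decline` per trait.
#' @export
cwm_trend <- function(object, grid, years = object$years,
                      swept_area = 0.047, correction = TRUE) {
  coords_new <- project_km(grid$lon, grid$lat, centre = object$centre)
  eta_pa <- .interp_spatial(object, object$pa$levels$spatial, coords_new)
  eta_abu <- .interp_spatial(object, object$abu$levels$spatial, coords_new)
  nd <- object$pa$n_draws
  traits <- object$traits
  trn <- c("age_maturity", "viviparous", "trophic_level")
  cwm <- array(NA_real_, c(length(years), 3, nd),
               dimnames = list(as.character(years), trn, NULL))
  for (yi in seq_along(years)) {
    X <- .grid_design(object, grid, years[yi], swept_area)
    pr <- .predict_linear(object, "pa", X, coords_new, years[yi],
                          stats::pnorm, eta_sp = eta_pa)
    mu <- .predict_linear(object, "abu", X, coords_new, years[yi],
                          identity, eta_sp = eta_abu)
    a <- pr * .back_transform(object, mu, correction)
    cw <- cwm_traits(a, traits)
    tot <- apply(a, c(1, 3), sum)                   # cell x draw weights
    for (ti in seq_along(trn)) {
      v <- cw[[ti]]
      cwm[yi, ti, ] <- colSums(v * tot, na.rm = TRUE) /
        colSums(tot * !is.na(v))
    }
  }
  qs <- apply(cwm, c(1, 2), stats::quantile,
              probs = c(0.025, 0.25, 0.75, 0.975))
  summary <- data.frame(
    year = rep(years, times = 3),
    trait = rep(trn, each = length(years)),
    mean = as.vector(apply(cwm, c(1, 2), mean)),
    q025 = as.vector(qs[1, , ]), q25 = as.vector(qs[2, , ]),
    q75 = as.vector(qs[3, , ]), q975 = as.vector(qs[4, , ]))
  pr_decline <- vapply(seq_along(trn), function(ti)
    mean(cwm[length(years), ti, ] < cwm[1, ti, ]), 0)
  names(pr_decline) <- trn
  list(cwm = cwm, summary = summary, pr_decline = pr_decline)
}
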