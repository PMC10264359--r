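# Simulation-based calibration of the Gibbs sampler: draw parameters from
# the exact priors the sampler uses, simulate data, sample the posterior,
# and record the rank of each true value among the posterior draws. If the
# sampler targets the correct joint distribution the ranks are uniform.

sbc_setup <- function() {
  n <- 12; p <- 3; years <- 1:3
  X <- cbind(intercept = 1, x = as.vector(scale(seq_len(n))))
  Tm <- cbind(intercept = 1, t1 = c(0, 1, 1))
  tax <- toy_taxonomy(3)
  tax$genus <- c("g1", "g2", "g2"); tax$family <- "f1"; tax$order <- "o1"
  C <- taxonomy_to_correlation(tax)
  coords <- cbind(x = c(0, 5, 10, 30, 35, 40, 80, 85, 90, 120, 125, 130),
                  y = c(0, 10, 20, 5, 15, 25, 0, 10, 20, 5, 15, 25))
  yr <- rep(years, length.out = n)
  ctrl <- mcmc_control(n_chains = 1, n_iter = 340, n_burnin = 100, thin = 8,
                       seed = 1, rho_grid = c(0, 0.5, 1),
                       n_factors_max = 1, gamma_var = 1,
                       alpha_every = 1,
                       shrink = list(nu = 3, a1 = 3, b1 = 1, a2 = 3, b2 = 1))
  ctrl$V_scale <- diag(2); ctrl$V_df <- 4
  sp_st <- hjsdm:::.spatial_struct(coords, alpha_grid = c(0, 40), mode = "full")
  sp_st$name <- "spatial"; sp_st$k_factors <- 1L
  tm_st <- hjsdm:::.temporal_struct(yr, length(years))
  tm_st$name <- "temporal"; tm_st$k_factors <- 1L
  miss <- matrix(FALSE, n, p); miss[c(2, 5, 9), 1] <- TRUE; miss[c(3, 11), 2] <- TRUE
  list(n = n, p = p, X = X, Tm = Tm, C = C, coords = coords, yr = yr,
       years = years, ctrl = ctrl, levels = list(spatial = sp_st,
                                                 temporal = tm_st),
       miss = miss)
}

sbc_prior_draw <- function(su) {
  p <- su$p; K <- ncol(su$X); q <- ncol(su$Tm)
  ctrl <- su$ctrl
  Gamma <- matrix(rnorm(q * K, 0, sqrt(ctrl$gamma_var)), q, K)
  V <- solve(stats::rWishart(1, ctrl$V_df, solve(ctrl$V_scale))[, , 1])
  rho <- sample(ctrl$rho_grid, 1)
  Sig <- rho * su$C + (1 - rho) * diag(p)
  M <- t(Gamma) %*% t(su$Tm)
  B <- M + t(chol(V)) %*% matrix(rnorm(K * p), K, p) %*% chol(Sig)
  sigma <- 1 / sqrt(stats::rgamma(p, ctrl$sigma_prior[1], ctrl$sigma_prior[2]))
  sh <- ctrl$shrink
  draw_level <- function(st) {
    phi <- matrix(stats::rgamma(p, sh$nu / 2, sh$nu / 2), 1, p)
    delta <- stats::rgamma(1, sh$a1, sh$b1)
    lam <- matrix(rnorm(p, 0, 1 / sqrt(phi * delta)), 1, p)
    if (st$type == "spatial") {
      a_idx <- sample(length(st$alpha_grid), 1)
      a <- st$alpha_grid[a_idx]
      eta <- if (a <= 0) rnorm(st$nu) else {
        Km <- exp(-as.matrix(stats::dist(st$coords)) / a) + diag(1e-6, st$nu)
        as.vector(t(chol(Km)) %*% rnorm(st$nu))
      }
    } else {
      a <- NA
      eta <- rnorm(st$nu)
    }
    list(lambda = lam, eta = matrix(eta, ncol = 1), alpha = a)
  }
  list(Gamma = Gamma, V = V, rho = rho, B = B, sigma = sigma,
       spatial = draw_level(su$levels$spatial),
       temporal = draw_level(su$levels$temporal))
}

sbc_simulate_y <- function(su, th) {
  L <- su$X %*% th$B +
    th$spatial$eta %*% th$spatial$lambda +
    th$temporal$eta[su$yr, , drop = FALSE] %*% th$temporal$lambda
  Y <- L + matrix(rnorm(su$n * su$p), su$n, su$p) %*% diag(th$sigma, su$p)
  Y[su$miss] <- NA
  colnames(Y) <- paste0("s", seq_len(su$p))
  Y
}

# uniform-rank of `truth` among `draws`, ties broken uniformly
sbc_rank <- function(draws, truth) {
  sum(draws < truth) + sample.int(sum(draws == truth) + 1L, 1L) - 1L
}

sbc_statistics <- function(post, th, d = NULL) {
  pull <- function(x) x                                   # readability
  ls <- post$levels$spatial; lt <- post$levels$temporal
  stats_of <- function(B, Gamma, V, rho, sigma, lam_s, eta_s, lam_t, eta_t) {
    c(B11 = B[1, 1], B21 = B[2, 1], B12 = B[1, 2], B22 = B[2, 2],
      B13 = B[1, 3], B23 = B[2, 3],
      G11 = Gamma[1, 1], G12 = Gamma[1, 2], G21 = Gamma[2, 1],
      G22 = Gamma[2, 2],
      V11 = V[1, 1], V22 = V[2, 2], V12 = V[1, 2],
      rho = rho, sigma1 = sigma[1],
      lam_s2 = lam_s[1]^2, lam_s_cross = lam_s[1] * lam_s[2],
      contrib_s = eta_s[1] * lam_s[1],
      lam_t2 = lam_t[1]^2, contrib_t = eta_t[1] * lam_t[1])
  }
  if (is.null(d)) {                       # truth
    stats_of(th$B, th$Gamma, th$V, th$rho, th$sigma,
             th$spatial$lambda[1, ], th$spatial$eta[, 1],
             th$temporal$lambda[1, ], th$temporal$eta[, 1])
  } else {
    stats_of(post$B[, , d], post$Gamma[, , d], post$V[, , d], post$rho[d],
             post$sigma[, d], post$levels$spatial$Lambda[1, , d],
             post$levels$spatial$eta[, 1, d],
             post$levels$temporal$Lambda[1, , d],
             post$levels$temporal$eta[, 1, d])
  }
}

sbc_run <- function(n_rep = 128, seed = 2024) {
  su <- sbc_setup()
  set.seed(seed)
  ranks <- NULL
  for (r in seq_len(n_rep)) {
    th <- sbc_prior_draw(su)
    Y <- sbc_simulate_y(su, th)
    ctrl <- su$ctrl
    ctrl$seed <- seed + 13L * r
    post <- hjsdm:::.gibbs_sampler(Y, "gaussian", su$X, su$Tm, su$C,
                                   su$levels, ctrl)
    truth <- sbc_statistics(post, th)
    mat <- vapply(seq_len(post$n_draws),
                  function(d) sbc_statistics(post, th, d),
                  numeric(length(truth)))
    rk <- vapply(seq_along(truth),
                 function(i) sbc_rank(mat[i, ], truth[i]), 0L)
    ranks <- rbind(ranks, rk)
  }
  colnames(ranks) <- names(sbc_statistics(NULL, sbc_prior_draw(su)))
  attr(ranks, "n_draws") <- 30L
  ranks
}

sbc_pvalues <- function(ranks) {
  M <- attr(ranks, "n_draws")
  apply(ranks, 2, function(r) {
    u <- (r + stats::runif(length(r))) / (M + 1)
    stats::ks.test(u, "punif")$p.value
  })
}
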