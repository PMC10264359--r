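# Direct checks of the sampler's conditional updates against closed forms
# and independent oracles.

test_that("probit latent draws match the truncated-normal law", {
  set.seed(1)
  n <- 40000
  # presence at linear predictor 0: half-normal, mean sqrt(2/pi)
  z <- hjsdm:::.rtnorm_pos(rep(0, n))
  expect_true(all(z > 0))
  expect_equal(mean(z), sqrt(2 / pi), tolerance = 0.01)
  # deep tail: truncation is negligible, z ~ N(L, 1)
  z2 <- hjsdm:::.rtnorm_neg(rep(-10, n))
  expect_equal(mean(z2), -10, tolerance = 0.02)
  expect_equal(sd(z2), 1, tolerance = 0.02)
  # signs always match the observation
  Y <- matrix(rbinom(200, 1, 0.5), 20, 10)
  L <- matrix(rnorm(200, 0, 2), 20, 10)
  z3 <- hjsdm:::.update_z_probit(Y, L)
  expect_true(all(z3[Y == 1] > 0) && all(z3[Y == 0] <= 0))
})

test_that("with flat traits and no factors the ABU model is conjugate ridge", {
  set.seed(42)
  n <- 400; p <- 2; K <- 3
  X <- cbind(1, scale(rnorm(n)), scale(rnorm(n)))
  colnames(X) <- c("intercept", "x1", "x2")
  Btrue <- matrix(c(0.5, 1, -1, -0.3, 0.4, 0.8), K, p)
  sigma <- c(0.7, 0.5)
  Y <- X %*% Btrue + matrix(rnorm(n * p), n, p) %*% diag(sigma)
  colnames(Y) <- c("a", "b")
  Vfix <- diag(c(2, 1, 1))
  Tm <- matrix(1, p, 1, dimnames = list(NULL, "intercept"))
  ctrl <- mcmc_control(n_chains = 2, n_iter = 2500, n_burnin = 500, thin = 2,
                       seed = 3, n_factors_max = 0,
                       fixed = list(V = Vfix, rho = 0, sigma = sigma,
                                    Gamma = matrix(0, 1, K)))
  ctrl$V_scale <- diag(K); ctrl$V_df <- K + 1
  post <- hjsdm:::.gibbs_sampler(Y, "gaussian", X, Tm, diag(p), list(), ctrl)
  for (j in 1:p) {
    A <- crossprod(X) / sigma[j]^2 + solve(Vfix)
    mean_cf <- solve(A, crossprod(X, Y[, j]) / sigma[j]^2)   # closed form
    cov_cf <- solve(A)
    expect_equal(unname(rowMeans(post$B[, j, ])), as.vector(mean_cf),
                 tolerance = 0.02, ignore_attr = TRUE)
    expect_equal(apply(post$B[, j, ], 1, var), diag(cov_cf),
                 tolerance = 0.15, ignore_attr = TRUE)
  }
})

test_that("PA sub-model with C = I and no factors matches an independent probit sampler", {
  set.seed(7)
  n <- 300; K <- 2
  X <- cbind(intercept = 1, x = as.vector(scale(rnorm(n))))
  btrue <- c(-0.4, 0.9)
  Y <- matrix((X %*% btrue + rnorm(n) > 0) * 1L, ncol = 1,
              dimnames = list(NULL, "a"))
  Vfix <- diag(2)
  Tm <- matrix(1, 1, 1, dimnames = list(NULL, "intercept"))
  ctrl <- mcmc_control(n_chains = 2, n_iter = 3000, n_burnin = 500, thin = 2,
                       seed = 5, n_factors_max = 0,
                       fixed = list(V = Vfix, rho = 0,
                                    Gamma = matrix(0, 1, K)))
  ctrl$V_scale <- diag(K); ctrl$V_df <- K + 1
  post <- hjsdm:::.gibbs_sampler(Y, "probit", X, Tm, diag(1), list(), ctrl)
  # independent oracle: plain Albert-Chib Gibbs probit with the same prior
  set.seed(99)
  b <- c(0, 0); keep <- matrix(NA_real_, 4000, 2)
  Vinv <- solve(Vfix); XtX <- crossprod(X)
  for (it in 1:5000) {
    L <- as.vector(X %*% b)
    z <- ifelse(Y[, 1] == 1, hjsdm:::.rtnorm_pos(L), hjsdm:::.rtnorm_neg(L))
    A <- XtX + Vinv
    ch <- chol(A)
    mu <- backsolve(ch, backsolve(ch, crossprod(X, z), transpose = TRUE))
    b <- as.vector(mu + backsolve(ch, rnorm(2)))
    if (it > 1000) keep[it - 1000, ] <- b
  }
  expect_equal(unname(rowMeans(post$B[, 1, ])), colMeans(keep),
               tolerance = 0.05)
  expect_equal(unname(apply(post$B[, 1, ], 1, sd)), apply(keep, 2, sd),
               tolerance = 0.1)
})

test_that("rho is unidentifiable when C = I: its posterior equals the prior", {
  set.seed(8)
  p <- 4; K <- 2
  B <- matrix(rnorm(K * p), K, p)
  Gamma <- matrix(0, 1, K)
  Tm <- matrix(1, p, 1)
  grid <- c(0, 0.5, 1)
  draws <- replicate(3000, hjsdm:::.update_rho(B, Gamma, Tm, diag(p),
                                               rep(1, p), diag(K), grid,
                                               rep(1 / 3, 3)))
  expect_equal(as.vector(table(factor(draws, levels = grid))) / 3000,
               rep(1 / 3, 3), tolerance = 0.05)
})

test_that("V draws with no species reproduce the inverse-Wishart prior", {
  set.seed(9)
  K <- 3; df <- K + 3                       # df large enough for a mean
  B <- matrix(numeric(0), K, 0)
  Gamma <- matrix(0, 1, K)
  Tm <- matrix(numeric(0), 0, 1)
  draws <- replicate(4000, hjsdm:::.update_V(B, Gamma, Tm,
                                             diag(0), numeric(0), 0,
                                             diag(K), df))
  # E[IW(I, df)] = I / (df - K - 1) = I / 2
  expect_equal(apply(draws, c(1, 2), mean), diag(K) / 2, tolerance = 0.08)
  expect_true(all(apply(draws, 3, function(v) min(eigen(v)$values) > 0)))
})

test_that("sigma draws concentrate on the residual scale", {
  set.seed(10)
  resid <- matrix(rnorm(5000 * 2, 0, 0.5), 5000, 2)
  draws <- replicate(200, hjsdm:::.update_sigma(resid, 1, 1))
  expect_equal(as.vector(rowMeans(draws)), rep(0.5, 2), tolerance = 0.05)
  # all-zero residuals: sigma collapses towards 0
  expect_lt(max(replicate(50, hjsdm:::.update_sigma(matrix(0, 5000, 1), 1, 1))),
            0.05)
})

test_that("the fit is bit-for-bit reproducible and scale invariant", {
  sim <- simulate_community(small_scenario())
  comm <- sim$community
  ctl <- mcmc_control(n_chains = 2, n_iter = 100, n_burnin = 40, thin = 2,
                      seed = 31, n_factors_max = 1)
  f1 <- hjsdm(comm, adriatic_traits(), adriatic_taxonomy(), mcmc = ctl)
  f2 <- hjsdm(comm, adriatic_traits(), adriatic_taxonomy(), mcmc = ctl)
  expect_identical(f1$pa$B, f2$pa$B)
  expect_identical(f1$abu$B, f2$abu$B)
  expect_identical(f1$abu$levels$spatial$eta, f2$abu$levels$spatial$eta)
  # multiplying one species' counts by a constant changes its scaled
  # responses only at floating-point precision (the standardization absorbs
  # the factor into m_j), so a short run from the same seed must agree to
  # numerical precision and (m, s) shift exactly as predicted
  comm2 <- comm
  sp1 <- species_columns(comm)[1]
  comm2[[sp1]] <- comm2[[sp1]] * 13L
  ctl2 <- mcmc_control(n_chains = 1, n_iter = 3, n_burnin = 1, thin = 1,
                       seed = 31, n_factors_max = 1)
  g1 <- hjsdm(comm, adriatic_traits(), adriatic_taxonomy(), mcmc = ctl2)
  g2 <- hjsdm(comm2, adriatic_traits(), adriatic_taxonomy(), mcmc = ctl2)
  expect_identical(g1$pa$B, g2$pa$B)       # PA never sees the counts' scale
  expect_equal(g1$abu$B, g2$abu$B, tolerance = 1e-8)
  expect_equal(g1$abu$levels$spatial$Lambda, g2$abu$levels$spatial$Lambda,
               tolerance = 1e-8)
  expect_equal(g2$hurdle$scale_params$m[1] - g1$hurdle$scale_params$m[1],
               log(13), tolerance = 1e-12)
  expect_equal(g2$hurdle$scale_params$s, g1$hurdle$scale_params$s)
})

test_that("rank-deficient designs are rejected with the collinear columns named", {
  sim <- simulate_community(small_scenario())
  comm <- sim$community
  comm$bot_temp <- 2 * log(comm$depth)       # exact collinearity
  expect_error(hjsdm(comm, adriatic_traits(), adriatic_taxonomy(),
                     mcmc = mcmc_control(n_iter = 20, n_burnin = 5, thin = 1,
                                         seed = 1)),
               "rank deficient")
})
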