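mk_fake <- function(Bdraws, X = NULL, groups = NULL, species = NULL, ...) {
  K <- dim(Bdraws)[1]; p <- dim(Bdraws)[2]
  if (is.null(species)) species <- paste0("s", seq_len(p))
  if (is.null(X)) {
    X <- cbind(intercept = rep(1, 8), x1 = seq(-1, 1, length.out = 8))
    groups <- c(intercept = "intercept", x1 = "g1")
  }
  dimnames(Bdraws)[1:2] <- list(colnames(X), species)
  fake_fit(B_pa = Bdraws, X = X, groups = groups, species = species, ...)
}

test_that("support classification counts positive draws", {
  nd <- 100
  B <- array(0, c(2, 2, nd))
  B[1, 1, ] <- abs(rnorm(nd)) + 0.01            # always positive
  B[2, 1, ] <- rep(c(-1, 1), nd / 2)            # symmetric
  B[1, 2, ] <- c(rep(1, 96), rep(-1, 4))        # 96 of 100 positive
  B[2, 2, ] <- c(rep(-1, 96), rep(1, 4))
  fit <- mk_fake(B)
  bs <- beta_support(fit, "pa", threshold = 0.95)
  get <- function(sp, cv) bs[bs$species == sp & bs$covariate == cv, ]
  expect_equal(get("s1", "intercept")$pr_positive, 1)
  expect_equal(get("s1", "intercept")$sign, "+")
  expect_equal(get("s1", "x1")$sign, "0")
  expect_equal(get("s2", "intercept")$pr_positive, 0.96)
  expect_equal(get("s2", "intercept")$sign, "+")
  expect_equal(get("s2", "x1")$sign, "-")
  # antisymmetry under negating every draw
  fit_neg <- mk_fake(-B)
  bs_neg <- beta_support(fit_neg, "pa", threshold = 0.95)
  flip <- c("+" = "-", "-" = "+", "0" = "0")
  expect_identical(unname(flip[bs$sign]), bs_neg$sign)
  expect_equal(bs_neg$mean, -bs$mean)
})

test_that("gamma support classifies trait effects the same way", {
  nd <- 120
  G <- array(rnorm(4 * 2 * nd, 0, 0.1), c(4, 2, nd))
  G[2, 1, ] <- abs(rnorm(nd)) + 0.1
  B <- array(rnorm(2 * 3 * nd), c(2, 3, nd))
  fit <- mk_fake(B, Gamma_pa = G)
  dimnames(fit$pa$Gamma)[1:2] <- list(c("intercept", "age_maturity",
                                        "repro_mode", "trophic_level"),
                                      c("intercept", "x1"))
  gs <- gamma_support(fit, "pa")
  row <- gs[gs$trait == "age_maturity" & gs$covariate == "intercept", ]
  expect_equal(row$pr_positive, 1)
  expect_equal(row$sign, "+")
  expect_true(all(gs$sign %in% c("+", "-", "0")))
})

test_that("variance partition attributes variance analytically", {
  # single covariate, no random levels: everything to that group
  nd <- 5
  B <- array(rep(c(0.3, 1.2), nd * 2), c(2, 2, nd))
  fit <- mk_fake(B)
  vp <- variance_partition(fit, "pa")
  expect_equal(unname(vp[, "g1"]), c(1, 1))
  expect_equal(unname(rowSums(vp)), c(1, 1))
  # two independent standardized covariates with equal |beta|: 50/50
  set.seed(5)
  n <- 2000
  x1 <- as.vector(scale(rnorm(n))); x2 <- as.vector(scale(rnorm(n)))
  X <- cbind(intercept = 1, x1 = x1, x2 = x2)
  groups <- c(intercept = "intercept", x1 = "g1", x2 = "g2")
  B2 <- array(rep(c(0, 1, -1), nd * 1), c(3, 1, nd))
  fit2 <- mk_fake(B2, X = X, groups = groups, species = "s1")
  vp2 <- variance_partition(fit2, "pa")
  expect_equal(unname(vp2[1, "g1"]), 0.5, tolerance = 0.05)
  expect_equal(unname(rowSums(vp2)), 1)
  # a dominant random level takes the largest share
  lev <- list(spatial = list(name = "spatial", type = "spatial",
                             k_factors = 1, nu = 8,
                             Lambda = array(3, c(1, 2, nd)),
                             eta = array(0, c(8, 1, nd))))
  fit3 <- mk_fake(B, levels_pa = lev)
  vp3 <- variance_partition(fit3, "pa")
  expect_true(all(vp3[, "random_spatial"] > vp3[, "g1"]))
  expect_equal(unname(rowSums(vp3)), c(1, 1))
  # intercept-only with no factors has no variance to partition
  B0 <- array(1, c(2, 2, nd)); B0[2, , ] <- 0
  expect_error(variance_partition(mk_fake(B0), "pa"), "zero total variance")
})

test_that("trait R2 is 1 when niches equal their trait prediction and 0 when traits are flat", {
  nd <- 6; p <- 5
  tr <- toy_traits(p)
  Tm <- cbind(1, tr$age_maturity, tr$repro_mode, tr$trophic_level)
  G <- matrix(c(0.2, -0.1, 0.5, 0.1, 0.3, -0.2, 0.05, 0), 4, 2)
  mu <- t(G) %*% t(Tm)                          # 2 x p deterministic niches
  B <- array(rep(mu, nd), c(2, p, nd))
  G_arr <- array(rep(G, nd), c(4, 2, nd))
  fit <- mk_fake(B, species = tr$species, traits = tr, Gamma_pa = G_arr)
  tv <- trait_r2(fit, "pa")
  expect_equal(unname(tv$per_covariate), rep(1, 2))
  expect_equal(tv$overall, 1)
  # zero Gamma with varying niches: traits explain nothing
  set.seed(6)
  B2 <- array(rnorm(2 * p * nd), c(2, p, nd))
  fit2 <- mk_fake(B2, species = tr$species, traits = tr,
                  Gamma_pa = array(0, c(4, 2, nd)))
  tv2 <- trait_r2(fit2, "pa")
  expect_equal(unname(tv2$per_covariate), rep(0, 2))
  expect_true(tv2$overall >= 0 && tv2$overall <= 1)
})

test_that("phylogenetic signal summarizes the rho draws by counting", {
  B <- array(rnorm(2 * 2 * 4), c(2, 2, 4))
  fit <- mk_fake(B, rho_pa = c(0, 0.5, 1, 0.5))
  ps <- phylo_signal(fit, "pa")
  expect_equal(unname(ps["mean"]), 0.5)
  expect_equal(unname(ps["pr_positive"]), 0.75)
  fit2 <- mk_fake(B, rho_pa = rep(0.5, 4))
  expect_equal(unname(phylo_signal(fit2, "pa")), c(0.5, 1))
  fit3 <- mk_fake(B, rho_pa = rep(0, 4))
  expect_equal(unname(phylo_signal(fit3, "pa")), c(0, 0))
})
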