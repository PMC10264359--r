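# fake two-species fit with known coefficients and no latent factors, for
# arithmetic-level prediction checks
pred_fake <- function(nd = 3, sigma = 0, m = c(1, 2), s = c(0.5, 1)) {
  X <- cbind(intercept = rep(1, 6), log_depth = log(seq(20, 120, length.out = 6)),
             bot_temp = seq(10, 20, length.out = 6), seabed_sand = rep(0:1, 3),
             log_swept_area = rep(log(0.047), 6),
             year_centered = rep(0, 6))
  groups <- c(intercept = "intercept", log_depth = "depth",
              bot_temp = "temperature", seabed_sand = "seabed",
              log_swept_area = "effort", year_centered = "year")
  B <- array(0, c(6, 2, nd))
  B[1, 1, ] <- 2; B[2, 1, ] <- -0.5             # species 1: depth-declining
  B[1, 2, ] <- -1; B[3, 2, ] <- 0.1             # species 2: warm-favouring
  fake_fit(B_pa = B, B_abu = B, X = X, groups = groups,
           species = c("s1", "s2"),
           sigma_abu = matrix(sigma, 2, nd), m = m, s = s)
}

test_that("occurrence prediction is the probit transform of the linear predictor", {
  fit <- pred_fake()
  g <- toy_grid(3)
  p <- predict(fit, g, year = 2000, type = "occurrence")
  # brute-force probit on the three cells
  Xg <- cbind(1, log(g$depth), g$bot_temp, as.numeric(g$seabed == "sand"),
              log(0.047), 0)
  Btrue <- fit$pa$B[, , 1]
  expect_equal(unname(p[, , 1]), unname(pnorm(Xg %*% Btrue)), tolerance = 1e-12)
  expect_true(all(p >= 0 & p <= 1))
  # linear predictor 0 gives probability one half
  fit0 <- pred_fake()
  fit0$pa$B[] <- 0
  p0 <- predict(fit0, g, year = 2000, type = "occurrence")
  expect_equal(as.vector(p0), rep(0.5, length(p0)))
  # strongly negative intercept drives occurrence to zero
  fitneg <- pred_fake(); fitneg$pa$B[1, , ] <- -40
  expect_lt(max(predict(fitneg, g, year = 2000, type = "occurrence")), 1e-20)
})

test_that("conditional abundance back-transforms with the lognormal correction", {
  fit <- pred_fake(sigma = 0.6, m = c(1, 2), s = c(0.5, 1))
  g <- toy_grid(3)
  cond <- predict(fit, g, year = 2000, type = "conditional")
  Xg <- cbind(1, log(g$depth), g$bot_temp, as.numeric(g$seabed == "sand"),
              log(0.047), 0)
  mu <- Xg %*% fit$abu$B[, , 1]
  manual <- exp(sweep(sweep(mu, 2, c(0.5, 1), "*"), 2, c(1, 2), "+") +
                  matrix(0.5 * c(0.5, 1)^2 * 0.6^2, 3, 2, byrow = TRUE))
  expect_equal(unname(cond[, , 1]), unname(manual), tolerance = 1e-12)
  # without correction: plain exponentiation; mu = 0, sigma = 0 -> exp(m)
  cond_nc <- predict(fit, g, year = 2000, type = "conditional",
                     correction = FALSE)
  expect_equal(unname(cond_nc[, , 1]),
               unname(exp(sweep(sweep(mu, 2, c(0.5, 1), "*"), 2, c(1, 2), "+"))),
               tolerance = 1e-12)
  fit0 <- pred_fake(sigma = 0); fit0$abu$B[] <- 0
  c0 <- predict(fit0, g, year = 2000, type = "conditional")
  expect_equal(unname(c0[, 1, 1]), rep(exp(1), 3))
  expect_equal(unname(c0[, 2, 1]), rep(exp(2), 3))
})

test_that("the lognormal mean correction matches brute-force Monte Carlo", {
  set.seed(9)
  m <- 1.3; s <- 0.7; mu <- 0.4; sig <- 0.5
  mc <- mean(exp(m + s * (mu + sig * rnorm(1e6))))
  expect_equal(exp(m + s * mu + 0.5 * s^2 * sig^2), mc, tolerance = 0.01)
})

test_that("expected abundance is the draw-wise hurdle product", {
  p <- array(c(0, 1, 0.5), c(3, 1, 2))
  cond <- array(4, c(3, 1, 2))
  a <- expected_abundance(p, cond)
  expect_equal(as.vector(a[, 1, 1]), c(0, 4, 2))
  expect_error(expected_abundance(p, array(1, c(2, 1, 2))))
  # monotone in both arguments
  expect_true(all(expected_abundance(p + 0.1, cond) >= a))
  expect_true(all(expected_abundance(p, cond + 1) >= a))
})

test_that("richness and pr_any follow from the occurrence probabilities", {
  p <- array(NA_real_, c(2, 2, 1))             # cell x species x draw
  p[1, , 1] <- c(1, 1); p[2, , 1] <- c(0, 0)
  r <- richness_and_any(p)
  expect_equal(as.vector(r$richness), c(2, 0))
  expect_equal(as.vector(r$pr_any), c(1, 0))
  # two species at one half: brute force over the four outcomes
  p2 <- array(0.5, c(1, 2, 1))
  r2 <- richness_and_any(p2)
  expect_equal(as.vector(r2$richness), 1)
  expect_equal(as.vector(r2$pr_any), 0.75)
  # invariants: pr_any >= max p, richness >= pr_any
  set.seed(10)
  p3 <- array(runif(5 * 4 * 6), c(5, 4, 6))
  r3 <- richness_and_any(p3)
  expect_true(all(r3$pr_any >= apply(p3, c(1, 3), max) - 1e-12))
  expect_true(all(r3$richness >= r3$pr_any - 1e-12))
})

test_that("community-weighted means are convex trait averages", {
  tr <- toy_traits(2, c("s1", "s2"))
  tr$age_maturity <- c(2, 6); tr$repro_mode <- c(0L, 1L)
  tr$trophic_level <- c(3.4, 4)
  a <- array(NA_real_, c(3, 2, 1))
  a[1, , 1] <- c(5, 0)           # single species present
  a[2, , 1] <- c(1, 3)           # weighted mean (1*2 + 3*6) / 4 = 5
  a[3, , 1] <- c(0, 0)           # empty cell
  cw <- cwm_traits(a, tr)
  expect_equal(cw$age_maturity[1, 1], 2)
  expect_equal(cw$viviparous[1, 1], 0)
  expect_equal(cw$age_maturity[2, 1], 5)
  expect_equal(cw$viviparous[2, 1], 0.75)
  expect_true(is.na(cw$age_maturity[3, 1]))
  # equal abundances of the nine reference species: community means match
  # the published table statistics
  tr9 <- adriatic_traits()
  a9 <- array(1, c(1, 9, 1))
  cw9 <- cwm_traits(a9, tr9)
  expect_equal(cw9$age_maturity[1, 1], mean(tr9$age_maturity))
  expect_equal(round(cw9$age_maturity[1, 1], 1), 7.1)
  expect_equal(round(cw9$trophic_level[1, 1], 2), 3.78)
  # convexity for arbitrary non-negative abundances
  set.seed(11)
  ar <- array(rexp(4 * 9 * 3), c(4, 9, 3))
  cwr <- cwm_traits(ar, tr9)
  expect_true(all(cwr$age_maturity >= min(tr9$age_maturity) - 1e-12 &
                  cwr$age_maturity <= max(tr9$age_maturity) + 1e-12))
  expect_true(all(cwr$trophic_level >= min(tr9$trophic_level) - 1e-12 &
                  cwr$trophic_level <= max(tr9$trophic_level) + 1e-12))
})

test_that("cell areas shrink with latitude as the cosine", {
  expect_equal(cell_areas(0), (0.05 * 111.32)^2, tolerance = 1e-12)
  expect_equal(cell_areas(0), 30.98, tolerance = 1e-3)
  expect_equal(cell_areas(60), cell_areas(0) / 2, tolerance = 1e-12)
  lats <- seq(0, 80, by = 5)
  expect_true(all(diff(cell_areas(lats)) < 0))
})

test_that("abundance indices are scaled to the baseline and scale invariant", {
  fit <- pred_fake(nd = 40)
  # add draw noise so the posterior is non-degenerate
  set.seed(12)
  fit$pa$B[1, , ] <- fit$pa$B[1, , ] + rnorm(2 * 40, 0, 0.1)
  fit$abu$B[1, , ] <- fit$abu$B[1, , ] + rnorm(2 * 40, 0, 0.1)
  fit$years <- 2000:2002
  g <- toy_grid(4)
  idx <- abundance_index(fit, g, years = 2000:2002, baseline_year = 2000)
  expect_equal(unname(apply(idx$index["2000", , ], 1, mean)), c(1, 1),
               tolerance = 1e-12)
  # multiplying all abundances by a constant (shift every m_j) changes nothing
  fit2 <- fit
  fit2$hurdle$scale_params$m <- fit2$hurdle$scale_params$m + log(7)
  idx2 <- abundance_index(fit2, g, years = 2000:2002, baseline_year = 2000)
  expect_equal(idx2$index, idx$index, tolerance = 1e-10)
  # a year-effect doubling abundance in the last year is recovered
  fit3 <- pred_fake(nd = 5)
  fit3$years <- 2000:2002
  # year_centered in 2002 is +2 (reference year 2000): s_j * B_year * 2 = log 2
  fit3$abu$B[6, , ] <- log(2) / fit3$hurdle$scale_params$s / 2
  idx3 <- abundance_index(fit3, g, years = c(2000, 2002),
                          baseline_year = 2000, correction = FALSE)
  expect_true(all(idx3$trend$direction == "increase"))
  expect_equal(idx3$trend$pr, c(1, 1))
})

test_that("grid prediction warns outside the fitted covariate range", {
  fit <- pred_fake()
  g <- toy_grid(3)
  g$depth[1] <- 5000
  expect_warning(predict(fit, g, year = 2000, type = "occurrence"),
                 "outside the fitted range")
})
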