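#' @export
print.hjsdm <- function(x, ...) {
  cat("Hurdle joint species distribution model (probit PA + Gaussian ABU)\n")
  cat(sprintf("  %d hauls, %d species, %d covariates, years %d-%d\n",
              nrow(x$design$X), length(x$species), ncol(x$design$X),
              min(x$years), max(x$years)))
  ctl <- x$manifest$control
  cat(sprintf("  %d chains x %d iterations (burn-in %d, thin %d): %d draws\n",
              ctl$n_chains, ctl$n_iter, ctl$n_burnin, ctl$thin, x$pa$n_draws))
  ps_pa <- phylo_signal(x, "pa"); ps_abu <- phylo_signal(x, "abu")
  cat(sprintf("  phylogenetic signal E[rho]: PA %.2f (Pr>0 %.2f), ABU %.2f (Pr>0 %.2f)\n",
              ps_pa["mean"], ps_pa["pr_positive"],
              ps_abu["mean"], ps_abu["pr_positive"]))
  invisible(x)
}

#' Summarize a fitted hurdle JSDM
#'
#' Explanatory fit (Tjur R2, AUC, ABU R2), convergence (split-chain PSRF by
#' parameter block), phylogenetic signal and mean variance shares.
#'
#' @param object an `hjsdm` fit.
#' @param ... unused.
#' @return a list of class `summary.hjsdm`.
#' @export
summary.hjsdm <- function(object, ...) {
  out <- list(fit = hjsdm_evaluate(object),
              psrf = psrf_summary(object),
              phylo = rbind(pa = phylo_signal(object, "pa"),
                            abu = phylo_signal(object, "abu")),
              varpart = lapply(c(pa = "pa", abu = "abu"), function(s)
                colMeans(variance_partition(object, s))))
  class(out) <- "summary.hjsdm"
  out
}

#' @export
print.summary.hjsdm <- function(x, ...) {
  cm <- attr(x$fit, "community_means")
  cat("Explanatory power (community means):\n")
  cat(sprintf("  Tjur R2 %.3f | AUC %.3f | ABU R2 %.3f\n",
              cm["tjur_r2"], cm["auc"], cm["r2"]))
  cat("Phylogenetic signal:\n")
  for (s in rownames(x$phylo))
    cat(sprintf("  %s: E[rho] = %.2f, Pr[rho > 0] = %.2f\n",
                toupper(s), x$phylo[s, "mean"], x$phylo[s, "pr_positive"]))
  cat("Mean variance shares:\n")
  for (s in names(x$varpart)) {
    v <- x$varpart[[s]]
    cat(sprintf("  %s: %s\n", toupper(s),
                paste(sprintf("%s %.0f%%", names(v), 100 * v), collapse = ", ")))
  }
  cat("Convergence (max split-chain PSRF by block):\n")
  agg <- stats::aggregate(max_psrf ~ submodel, x$psrf, max)
  for (i in seq_len(nrow(agg)))
    cat(sprintf("  %s: %.3f\n", toupper(agg$submodel[i]), agg$max_psrf[i]))
  invisible(x)
}

#' Posterior-mean coefficients
#'
#' @param object an `hjsdm` fit.
#' @param submodel `"pa"` or `"abu"`.
#' @param which `"beta"` (covariate x species niches) or `"gamma"`
#'   (trait x covariate effects).
#' @param ... unused.
#' @return posterior-mean matrix.
#' @export
coef.hjsdm <- function(object, submodel = c("pa", "abu"),
                       which = c("beta", "gamma"), ...) {
  submodel <- match.arg(submodel); which <- match.arg(which)
  post <- object[[submodel]]
  apply(if (which == "beta") post$B else post$Gamma, c(1, 2), mean)
}

#' Response residuals of a fitted hurdle JSDM
#'
#' PA: observed presence minus posterior-mean occurrence probability; ABU:
#' observed scaled log abundance minus posterior-mean latent prediction (NA
#' at absences).
#'
#' @inheritParams coef.hjsdm
#' @return haul x species matrix.
#' @export
residuals.hjsdm <- function(object, submodel = c("pa", "abu"), ...) {
  submodel <- match.arg(submodel)
  f <- fitted(object, submodel)
  if (submodel == "pa") object$hurdle$Y_pa - f else object$hurdle$Y_abu - f
}

#' Posterior-predictive simulation of community tables
#'
#' Draws `nsim` replicate surveys at the observed hauls: for each replicate a
#' posterior draw is selected, presence is Bernoulli at its occurrence
#' probability, and counts at presences are generated from the lognormal
#' conditional-abundance model (rounded, floored at 1).
#'
#' @param object an `hjsdm` fit.
#' @param nsim number of replicate tables.
#' @param seed optional seed.
#' @param ... unused.
#' @return list of community tables.
#' @export
simulate.hjsdm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(object$design$X); p <- length(object$species)
  X <- object$design$X
  sp <- object$hurdle$scale_params
  base <- object$community[setdiff(names(object$community),
                                   species_columns(object$community))]
  draws <- sample.int(object$pa$n_draws, nsim, replace = TRUE)
  lapply(draws, function(d) {
    L_pa <- X %*% object$pa$B[, , d] + .insample_factors(object, "pa", d)
    L_abu <- X %*% object$abu$B[, , d] + .insample_factors(object, "abu", d)
    pres <- (L_pa + matrix(stats::rnorm(n * p), n, p)) > 0
    v <- L_abu + matrix(stats::rnorm(n * p), n, p) %*%
      diag(object$abu$sigma[, d], p)
    counts <- ifelse(pres,
                     pmax(1, round(exp(sweep(sweep(v, 2, sp$s, "*"),
                                             2, sp$m, "+")))), 0)
    colnames(counts) <- paste0("sp_", object$species)
    cbind(base, as.data.frame(counts))
  })
}

.insample_factors <- function(object, submodel, d) {
  post <- object[[submodel]]
  n <- nrow(object$design$X); p <- length(object$species)
  FC <- matrix(0, n, p)
  for (lev in post$levels) {
    if (lev$k_factors == 0) next
    eta <- matrix(lev$eta[, , d], ncol = lev$k_factors)
    if (lev$type == "iid")
      eta <- eta[match(object$community$year, object$years), , drop = FALSE]
    FC <- FC + eta %*% matrix(lev$Lambda[, , d], nrow = lev$k_factors)
  }
  FC
}

#' Heatmap of posterior niche support
#'
#' Displays the sign classification of [beta_support()]: red for positive,
#' blue for negative responses with the requested posterior support, white
#' otherwise.
#'
#' @param x an `hjsdm` fit.
#' @param submodel `"pa"` or `"abu"`.
#' @param threshold support threshold.
#' @param ... passed to [graphics::image()].
#' @export
plot.hjsdm <- function(x, submodel = c("pa", "abu"), threshold = 0.95, ...) {
  submodel <- match.arg(submodel)
  bs <- beta_support(x, submodel, threshold)
  covs <- unique(bs$covariate); sps <- unique(bs$species)
  z <- matrix(0, length(covs), length(sps))
  z[cbind(match(bs$covariate, covs), match(bs$species, sps))] <-
    ifelse(bs$sign == "+", 1, ifelse(bs$sign == "-", -1, 0))
  op <- graphics::par(mar = c(8, 8, 2, 1)); on.exit(graphics::par(op))
  graphics::image(seq_along(covs), seq_along(sps), z, zlim = c(-1, 1),
                  col = c("#2166AC", "white", "#B2182B"),
                  axes = FALSE, xlab = "", ylab = "",
                  main = paste("Niche support,", toupper(submodel)), ...)
  graphics::axis(1, seq_along(covs), covs, las = 2)
  graphics::axis(2, seq_along(sps), sps, las = 2)
  graphics::box()
  invisible(x)
}
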