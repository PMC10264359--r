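.support_sign <- function(pr_pos, threshold) {
  ifelse(pr_pos >= threshold, "+", ifelse(1 - pr_pos >= threshold, "-", "0"))
}

#' Posterior support of the species niches (beta)
#'
#' Per species and covariate: posterior mean, posterior probability of a
#' positive effect, and a sign classification (`+`/`-` when that probability
#' reaches the support threshold, else `0`), mirroring the convention of
#' reporting responses with at least 95% posterior probability.
#'
#' @param object an `hjsdm` fit.
#' @param submodel `"pa"` or `"abu"`.
#' @param threshold posterior-probability support threshold (default 0.95).
#' @return long `data.frame`: `species`, `covariate`, `mean`, `pr_positive`,
#'   `sign`.
#' @export
beta_support <- function(object, submodel = c("pa", "abu"), threshold = 0.95) {
  submodel <- match.arg(submodel)
  post <- object[[submodel]]
  if (post$n_draws < 100)
    warning("fewer than 100 posterior draws; support estimates are coarse")
  .support_table(post$B, rows = "covariate", cols = "species", threshold)
}

#' Posterior support of the trait effects (gamma)
#'
#' Same classification as [beta_support()] applied to the trait x covariate
#' effects linking species traits to their environmental responses.
#'
#' @inheritParams beta_support
#' @return long `data.frame`: `trait`, `covariate`, `mean`, `pr_positive`,
#'   `sign`.
#' @export
gamma_support <- function(object, submodel = c("pa", "abu"), threshold = 0.95) {
  submodel <- match.arg(submodel)
  post <- object[[submodel]]
  if (post$n_draws < 100)
    warning("fewer than 100 posterior draws; support estimates are coarse")
  .support_table(post$Gamma, rows = "trait", cols = "covariate", threshold)
}

.support_table <- function(arr, rows, cols, threshold) {
  mn <- apply(arr, c(1, 2), mean)
  pr <- apply(arr, c(1, 2), function(v) mean(v > 0))
  out <- data.frame(
    r = rep(rownames(mn), times = ncol(mn)),
    c = rep(colnames(mn), each = nrow(mn)),
    mean = as.vector(mn), pr_positive = as.vector(pr),
    sign = .support_sign(as.vector(pr), threshold),
    stringsAsFactors = FALSE)
  names(out)[1:2] <- c(rows, cols)
  out
}

#' Partition explained variance over covariate groups and random levels
#'
#' Per posterior draw and species, the fixed-effect variance attributed to a
#' covariate group is the variance over hauls of that group's contribution
#' `X_g B_gj`; each random level contributes its loading sum of squares
#' `sum_h Lambda_hj^2` (the factors have unit marginal variance). Fractions
#' of the per-draw total are averaged over draws and renormalized, so they
#' sum to one per species. The constant intercept contributes no variance
#' and is omitted.
#'
#' @inheritParams beta_support
#' @return matrix species x component with an attribute `components`; rows
#'   sum to 1.
#' @export
variance_partition <- function(object, submodel = c("pa", "abu")) {
  submodel <- match.arg(submodel)
  post <- object[[submodel]]
  X <- object$design$X
  groups <- object$design$groups
  gset <- setdiff(unique(groups), "intercept")
  lev_names <- paste0("random_", names(post$levels))
  comp <- c(gset, lev_names)
  p <- length(object$species)
  acc <- matrix(0, p, length(comp), dimnames = list(object$species, comp))
  for (d in seq_len(post$n_draws)) {
    vmat <- matrix(0, p, length(comp))
    for (gi in seq_along(gset)) {
      cols <- names(groups)[groups == gset[gi]]
      Bg <- matrix(post$B[cols, , d], nrow = length(cols))
      contrib <- X[, cols, drop = FALSE] %*% Bg
      vmat[, gi] <- apply(contrib, 2, stats::var)
    }
    for (li in seq_along(post$levels)) {
      lam <- post$levels[[li]]$Lambda[, , d, drop = FALSE]
      dim(lam) <- dim(post$levels[[li]]$Lambda)[1:2]
      vmat[, length(gset) + li] <- colSums(lam^2)
    }
    tot <- rowSums(vmat)
    if (any(tot == 0))
      stop("zero total variance for at least one species ",
           "(intercept-only model with no latent factors?)")
    acc <- acc + vmat / tot
  }
  out <- acc / post$n_draws
  out <- out / rowSums(out)
  attr(out, "components") <- comp
  class(out) <- c("hjsdm_varpart", class(out))
  out
}

#' Share of niche variation explained by traits
#'
#' Per covariate `k` and draw, the fraction of the across-species variance of
#' the niches `B_k.` captured by their trait-based expectation
#' `mu = t(Gamma) t(T')`, clipped to `[0, 1]`. The overall share is the
#' weighted mean of the per-covariate fractions, weighted by each
#' covariate's mean share of explained variance (from
#' [variance_partition()]); everything is averaged over draws.
#'
#' @inheritParams beta_support
#' @return list with `per_covariate` (named vector) and `overall` (scalar).
#' @export
trait_r2 <- function(object, submodel = c("pa", "abu")) {
  submodel <- match.arg(submodel)
  post <- object[[submodel]]
  if (length(object$species) < 2)
    stop("trait_r2 is undefined with a single species")
  Tm <- .trait_design(object$traits)
  K <- dim(post$B)[1]
  covn <- dimnames(post$B)[[1]]
  r2 <- matrix(NA_real_, post$n_draws, K, dimnames = list(NULL, covn))
  for (d in seq_len(post$n_draws)) {
    mu <- t(post$Gamma[, , d]) %*% t(Tm)           # K x p expected niches
    for (k in seq_len(K)) {
      vb <- stats::var(post$B[k, , d])
      r2[d, k] <- if (vb > 0) min(1, max(0, stats::var(mu[k, ]) / vb)) else NA
    }
  }
  per_cov <- colMeans(r2, na.rm = TRUE)
  vp <- variance_partition(object, submodel)
  groups <- object$design$groups
  w <- vapply(covn, function(cn) {
    g <- groups[[cn]]
    if (g %in% colnames(vp)) mean(vp[, g]) else 0   # intercept gets weight 0
  }, 0)
  usable <- w > 0 & !is.na(per_cov)
  list(per_covariate = per_cov,
       overall = sum(w[usable] * per_cov[usable]) / sum(w[usable]))
}

#' Phylogenetic signal in the residual niches
#'
#' Posterior mean of the signal-strength parameter rho and the posterior
#' probability that it is strictly positive (the prior grid includes 0).
#'
#' @inheritParams beta_support
#' @return named vector `c(mean, pr_positive)`.
#' @export
phylo_signal <- function(object, submodel = c("pa", "abu")) {
  submodel <- match.arg(submodel)
  rho <- object[[submodel]]$rho
  c(mean = mean(rho), pr_positive = mean(rho > 0))
}
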