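#' Split-chain potential scale reduction factor
#'
#' Gelman-Rubin convergence diagnostic with each chain split in half (the
#' modern, more conservative variant), so within-chain trends register as
#' between-chain variance. Values near 1 indicate convergence.
#'
#' @param x draws of a scalar parameter: a matrix (iterations x chains) or a
#'   list of equal-length numeric vectors.
#' @return the PSRF (>= 1 up to floating point).
#' @export
psrf <- function(x) {
  if (is.list(x)) x <- do.call(cbind, x)
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("psrf needs at least 2 chains")
  if (nrow(x) < 4) stop("psrf needs at least 4 draws per chain")
  half <- floor(nrow(x) / 2)
  x <- cbind(x[seq_len(half), , drop = FALSE],
             x[nrow(x) - half + seq_len(half), , drop = FALSE])
  n <- nrow(x)
  W <- mean(apply(x, 2, stats::var))
  B <- n * stats::var(colMeans(x))
  if (W == 0 || !is.finite(W)) {
    if (B == 0) {                    # fully degenerate: all values identical
      warning("zero within- and between-chain variance; returning PSRF = 1")
      return(1)
    }
    warning("zero within-chain variance with distinct chain levels")
    return(Inf)
  }
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Tjur's coefficient of discrimination
#'
#' Mean predicted occurrence probability at presences minus the mean at
#' absences; 1 for perfect discrimination, 0 for none.
#'
#' @param p predicted probabilities.
#' @param y observed 0/1.
#' @return scalar in `[-1, 1]`, or `NA` when only one class is observed.
#' @export
tjur_r2 <- function(p, y) {
  stopifnot(length(p) == length(y))
  if (length(unique(y)) < 2) return(NA_real_)
  mean(p[y == 1]) - mean(p[y == 0])
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Probability that a randomly chosen presence is ranked above a randomly
#' chosen absence; ties count one half. Invariant to any strictly increasing
#' transform of the predictions.
#'
#' @inheritParams tjur_r2
#' @return scalar in `[0, 1]`, or `NA` when only one class is observed.
#' @export
auc_mw <- function(p, y) {
  stopifnot(length(p) == length(y))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(p)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Explanatory R-squared of the conditional-abundance model
#'
#' Squared Pearson correlation between the posterior-mean prediction and the
#' observed scaled log abundance over presence hauls.
#'
#' @param pred posterior-mean predictions.
#' @param obs observations (NA allowed; pairs with NA are dropped).
#' @return scalar in `[0, 1]`, or `NA` with fewer than 3 presence rows.
#' @export
abu_r2 <- function(pred, obs) {
  ok <- !is.na(pred) & !is.na(obs)
  if (sum(ok) < 3) return(NA_real_)
  stats::cor(pred[ok], obs[ok])^2
}

#' In-sample posterior-mean predictions of a fitted model
#'
#' For the PA sub-model, the posterior mean over draws of the draw-wise
#' occurrence probability `Phi(L)`; for ABU, the posterior mean latent
#' prediction on the scaled log-abundance scale.
#'
#' @param object an `hjsdm` fit.
#' @param submodel `"pa"` or `"abu"`.
#' @param ... unused.
#' @return haul x species matrix.
#' @export
fitted.hjsdm <- function(object, submodel = c("pa", "abu"), ...) {
  submodel <- match.arg(submodel)
  post <- object[[submodel]]
  n <- nrow(object$design$X); p <- length(object$species)
  acc <- matrix(0, n, p)
  for (d in seq_len(post$n_draws)) {
    L <- object$design$X %*% post$B[, , d]
    for (lev in post$levels) {
      eta <- lev$eta[, , d, drop = FALSE]
      dim(eta) <- dim(lev$eta)[1:2]
      eta_h <- if (lev$type == "iid") eta[match(object$community$year,
                                                object$years), , drop = FALSE]
               else eta
      if (lev$k_factors > 0) {
        Lam <- lev$Lambda[, , d, drop = FALSE]
        dim(Lam) <- dim(lev$Lambda)[1:2]
        L <- L + eta_h %*% Lam
      }
    }
    acc <- acc + (if (submodel == "pa") stats::pnorm(L) else L)
  }
  out <- acc / post$n_draws
  dimnames(out) <- dimnames(object$hurdle$Y_pa)
  out
}

#' Explanatory fit metrics per species
#'
#' Tjur R2 and AUC of the PA sub-model and R2 of the ABU sub-model, from
#' in-sample posterior-mean predictions, plus their community (arithmetic)
#' means.
#'
#' @param object an `hjsdm` fit.
#' @return `data.frame` (species x metric) with attribute
#'   `community_means`.
#' @export
hjsdm_evaluate <- function(object) {
  p_hat <- fitted(object, "pa")
  a_hat <- fitted(object, "abu")
  Y_pa <- object$hurdle$Y_pa
  Y_abu <- object$hurdle$Y_abu
  res <- data.frame(
    species = object$species,
    tjur_r2 = vapply(seq_along(object$species),
                     function(j) tjur_r2(p_hat[, j], Y_pa[, j]), 0),
    auc = vapply(seq_along(object$species),
                 function(j) auc_mw(p_hat[, j], Y_pa[, j]), 0),
    r2 = vapply(seq_along(object$species),
                function(j) abu_r2(a_hat[Y_pa[, j] == 1, j],
                                   Y_abu[Y_pa[, j] == 1, j]), 0),
    row.names = NULL)
  attr(res, "community_means") <- c(tjur_r2 = mean(res$tjur_r2, na.rm = TRUE),
                                    auc = mean(res$auc, na.rm = TRUE),
                                    r2 = mean(res$r2, na.rm = TRUE))
  res
}

#' PSRF summary over parameter blocks
#'
#' Applies the split-chain PSRF element-wise to the main parameter blocks of
#' both sub-models and reports the mean and maximum per block.
#'
#' @param object an `hjsdm` fit.
#' @return `data.frame` with columns `submodel`, `block`, `mean_psrf`,
#'   `max_psrf`.
#' @export
psrf_summary <- function(object) {
  out <- list()
  for (sub in c("pa", "abu")) {
    post <- object[[sub]]
    chains <- post$chain
    per_chain <- function(v) split(v, chains)  # draw vector -> list by chain
    blocks <- list(
      beta = apply(post$B, c(1, 2), identity),
      gamma = apply(post$Gamma, c(1, 2), identity),
      rho = matrix(post$rho, ncol = 1))
    for (bn in names(blocks)) {
      b <- blocks[[bn]]
      b <- matrix(b, nrow = post$n_draws)
      vals <- apply(b, 2, function(v) {
        suppressWarnings(psrf(do.call(cbind, per_chain(v))))
      })
      out[[length(out) + 1]] <- data.frame(submodel = sub, block = bn,
                                           mean_psrf = mean(vals),
                                           max_psrf = max(vals))
    }
  }
  do.call(rbind, out)
}
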