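# Internal blocked Gibbs machinery shared by the PA (probit) and ABU
# (Gaussian on scaled log abundance) sub-models.
#
# Model, per sub-model:
#   z = X B + sum_l eta_l[unit_l, ] Lambda_l + eps,   eps_ij ~ N(0, sigma_j^2)
#   probit: z is the latent response (sigma = 1, y = 1[z > 0]);
#   gaussian: z equals the observed scaled log abundance where present and is
#   imputed from its conditional where absent (exact augmentation).
#   B ~ MN(t(Gamma) t(T'), V, rho C + (1 - rho) I),  Gamma ~ N(0, gamma_var I)
#   V ~ IW(I, K + 1); rho uniform on a grid; sigma_j^2 ~ IG(1, 1)
#   eta: unit-variance GP (spatial, exponential kernel, range alpha on a
#   grid) or i.i.d. (temporal); Lambda under multiplicative-gamma shrinkage.

# --- truncated/imputed latent response -------------------------------------

# one-sided truncated normal N(mean, 1) via the survival function: accurate
# far into the tails (e.g. mean = -10 truncated to (0, Inf))
.rtnorm_pos <- function(mean) {
  mean + stats::qnorm(stats::runif(length(mean)) * stats::pnorm(mean),
                      lower.tail = FALSE)
}
.rtnorm_neg <- function(mean) {
  -.rtnorm_pos(-mean)
}

.update_z_probit <- function(Y, L) {
  z <- L
  pos <- Y > 0
  z[pos] <- .rtnorm_pos(L[pos])
  z[!pos] <- .rtnorm_neg(L[!pos])
  z
}

.update_z_gaussian <- function(Y, L, sigma, obs_mask) {
  z <- Y
  miss <- !obs_mask
  if (any(miss)) {
    sig <- matrix(sigma, nrow(Y), ncol(Y), byrow = TRUE)
    z[miss] <- L[miss] + stats::rnorm(sum(miss)) * sig[miss]
  }
  z
}

# --- (B, Gamma) joint conjugate draw ---------------------------------------

# Zt: latent response minus latent-factor contribution (n x p)
# Returns list(B = K x p, Gamma = q x K). When `fixed_Gamma` is supplied the
# draw is B | Gamma (test mode); otherwise (B, Gamma) are drawn jointly from
# their exact multivariate-normal full conditional.
.update_beta_gamma <- function(Zt, X, XtX, Tm, EC, lamC, rho, V, w, gamma_var,
                               fixed_Gamma = NULL) {
  K <- ncol(X); p <- ncol(Zt); q <- ncol(Tm)
  Vinv <- .safe_inv(V, "V")
  s <- rho * lamC + (1 - rho)
  SrhoInv <- EC %*% (t(EC) / s)
  PB <- kronecker(SrhoInv, Vinv)                     # (Kp) x (Kp)
  DX <- kronecker(diag(w, p), XtX)
  M1 <- crossprod(X, Zt)                             # K x p
  lb <- as.vector(M1 %*% diag(w, p))
  if (!is.null(fixed_Gamma)) {
    Mv <- as.vector(t(fixed_Gamma) %*% t(Tm))        # vec of prior mean K x p
    ch <- .safe_chol(PB + DX, "B precision")
    rhs <- lb + PB %*% Mv
    mu <- backsolve(ch, backsolve(ch, rhs, transpose = TRUE))
    b <- mu + backsolve(ch, stats::rnorm(K * p))
    return(list(B = matrix(b, K, p), Gamma = fixed_Gamma))
  }
  ST <- SrhoInv %*% Tm                               # p x q
  PBA <- kronecker(ST, Vinv)                         # (Kp) x (Kq)
  AtPBA <- kronecker(crossprod(Tm, ST), Vinv)        # (Kq) x (Kq)
  prec <- rbind(cbind(PB + DX, -PBA),
                cbind(t(-PBA), diag(1 / gamma_var, K * q) + AtPBA))
  ch <- .safe_chol(prec, "joint (B, Gamma) precision")
  mu <- backsolve(ch, backsolve(ch, c(lb, rep(0, K * q)), transpose = TRUE))
  theta <- mu + backsolve(ch, stats::rnorm(K * (p + q)))
  list(B = matrix(theta[seq_len(K * p)], K, p),
       Gamma = t(matrix(theta[-seq_len(K * p)], K, q)))
}

.safe_chol <- function(A, what, jitter = 1e-8) {
  tryCatch(chol(A), error = function(e) {
    warning("jittering non-PSD ", what, " by ", jitter)
    chol(A + jitter * mean(diag(A)) * diag(nrow(A)))
  })
}

.safe_inv <- function(A, what) {
  ch <- .safe_chol(A, what)
  chol2inv(ch)
}

# --- V and rho --------------------------------------------------------------

.update_V <- function(B, Gamma, Tm, EC, lamC, rho, V0_scale, V0_df) {
  K <- nrow(B); p <- ncol(B)
  R <- B - t(Gamma) %*% t(Tm)
  s <- rho * lamC + (1 - rho)
  SrhoInv <- EC %*% (t(EC) / s)
  S <- R %*% SrhoInv %*% t(R)
  Psi <- V0_scale + (S + t(S)) / 2
  df <- V0_df + p
  W <- stats::rWishart(1, df, .safe_inv(Psi, "IW scale"))[, , 1]
  .safe_inv(W, "Wishart draw")
}

.update_rho <- function(B, Gamma, Tm, EC, lamC, V, rho_grid, rho_prior) {
  K <- nrow(B)
  R <- B - t(Gamma) %*% t(Tm)
  Vinv <- .safe_inv(V, "V")
  RE <- R %*% EC                                    # K x p, eigenbasis of C
  qv <- colSums(RE * (Vinv %*% RE))                 # quadratic form per eigdir
  ll <- vapply(rho_grid, function(r) {
    s <- r * lamC + (1 - r)
    -0.5 * (K * sum(log(s)) + sum(qv / s))
  }, 0)
  lw <- ll + log(rho_prior)
  if (all(!is.finite(lw))) stop("rho update: all grid likelihoods are -Inf")
  w <- exp(lw - max(lw))
  rho_grid[sample.int(length(rho_grid), 1L, prob = w)]
}

# --- residual variances (ABU) ----------------------------------------------

.update_sigma <- function(resid, a0, b0) {
  n <- nrow(resid)
  ss <- colSums(resid^2)
  shape <- a0 + n / 2
  rate <- b0 + ss / 2
  sqrt(1 / stats::rgamma(length(ss), shape = shape, rate = rate))
}

# --- latent factors ---------------------------------------------------------

# Spatial level structure: eigendecompositions (full mode) or predictive-
# process projections (knot mode) for every candidate range alpha, computed
# once and shared across chains and sub-models.
.spatial_struct <- function(coords_km, alpha_grid, mode = c("full", "predictive"),
                            n_knots = 64, alpha_prior = NULL, jitter = 1e-6) {
  mode <- match.arg(mode)
  n <- nrow(coords_km)
  stopifnot(alpha_grid[1] == 0, !is.unsorted(alpha_grid))
  if (is.null(alpha_prior)) alpha_prior <- rep(1 / length(alpha_grid), length(alpha_grid))
  st <- list(type = "spatial", mode = mode, nu = n, identity_map = TRUE,
             alpha_grid = alpha_grid, alpha_prior = alpha_prior,
             coords = coords_km)
  if (mode == "full") {
    d <- as.matrix(stats::dist(coords_km))
    st$eig <- lapply(alpha_grid, function(a) {
      if (a <= 0) return(NULL)                      # identity covariance
      e <- eigen(exp(-d / a) + diag(jitter, n), symmetric = TRUE)
      list(U = e$vectors, d = pmax(e$values, jitter))
    })
  } else {
    if (n_knots < 4) stop("predictive Gaussian process needs at least 4 knots")
    # the degenerate alpha = 0 entry has no knot representation; the
    # predictive grid starts at the smallest positive candidate range
    keep <- alpha_grid > 0
    alpha_prior <- alpha_prior[keep] / sum(alpha_prior[keep])
    alpha_grid <- alpha_grid[keep]
    st$alpha_grid <- alpha_grid
    st$alpha_prior <- alpha_prior
    side <- ceiling(sqrt(n_knots))
    kx <- seq(min(coords_km[, 1]), max(coords_km[, 1]), length.out = side)
    ky <- seq(min(coords_km[, 2]), max(coords_km[, 2]), length.out = side)
    kn <- as.matrix(expand.grid(x = kx, y = ky))
    m <- nrow(kn)
    st$knots <- kn
    st$pp <- lapply(alpha_grid, function(a) {
      if (a <= 0) return(NULL)
      Kmm <- exp(-as.matrix(stats::dist(kn)) / a) + diag(jitter, m)
      Knm <- exp(-.cross_dist(coords_km, kn) / a)
      ch <- chol(Kmm)
      P <- Knm %*% chol2inv(ch)                     # n x m projector
      list(cholKmm = ch, KmmInv = chol2inv(ch), P = P, PtP = crossprod(P),
           logdetKmm = 2 * sum(log(diag(ch))))
    })
  }
  st
}

.cross_dist <- function(a, b) {
  sqrt(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b))
}

.temporal_struct <- function(unit, nu) {
  list(type = "iid", nu = nu, identity_map = FALSE, unit = unit,
       counts = tabulate(unit, nu))
}

# One Gibbs pass over the factors of one level. `Ehat` is z - X B minus the
# contributions of the *other* levels. Returns updated level state.
.update_level_factors <- function(ls, st, Ehat, w, update_alpha) {
  k <- ls$k
  if (k == 0) return(ls)
  lamw <- ls$Lambda * rep(w, each = k)              # k x p, loadings * 1/sig^2
  for (h in seq_len(k)) {
    contrib_minus <- if (k > 1) {
      hh <- seq_len(k)[-h]
      .map_units(ls$eta[, hh, drop = FALSE], st) %*% ls$Lambda[hh, , drop = FALSE]
    } else 0
    R <- Ehat - contrib_minus
    b_haul <- as.vector(R %*% lamw[h, ])            # length n
    cc <- sum(ls$Lambda[h, ]^2 * w)
    if (st$type == "iid") {
      tmp <- rowsum(b_haul, st$unit)                # one row per observed unit
      bu <- numeric(st$nu); bu[as.integer(rownames(tmp))] <- tmp[, 1]
      prec <- 1 + cc * st$counts
      ls$eta[, h] <- bu / prec + stats::rnorm(st$nu) / sqrt(prec)
    } else if (st$mode == "full") {
      a <- ls$alpha_idx[h]
      if (st$alpha_grid[a] <= 0) {
        prec <- 1 + cc
        y <- b_haul / prec + stats::rnorm(st$nu) / sqrt(prec)
        ls$eta[, h] <- y
        ls$coef[[h]] <- y                           # eigenbasis = identity
      } else {
        e <- st$eig[[a]]
        v <- 1 / (1 / e$d + cc)
        y <- v * crossprod(e$U, b_haul)[, 1] + sqrt(v) * stats::rnorm(st$nu)
        ls$eta[, h] <- e$U %*% y
        ls$coef[[h]] <- y                           # cached U' eta for alpha move
      }
    } else {                                        # predictive process
      a <- ls$alpha_idx[h]
      if (st$alpha_grid[a] <= 0) {
        prec <- 1 + cc
        ls$eta_knots[, h] <- 0
        ls$eta[, h] <- b_haul / prec + stats::rnorm(st$nu) / sqrt(prec)
      } else {
        pp <- st$pp[[a]]
        m <- ncol(pp$P)
        prec <- pp$KmmInv + cc * pp$PtP
        ch <- .safe_chol(prec, "predictive-process precision")
        rhs <- crossprod(pp$P, b_haul)[, 1]
        mu <- backsolve(ch, backsolve(ch, rhs, transpose = TRUE))
        es <- mu + backsolve(ch, stats::rnorm(m))
        ls$eta_knots[, h] <- es
        ls$eta[, h] <- pp$P %*% es
      }
    }
  }
  if (st$type == "spatial" && update_alpha) ls <- .update_alpha(ls, st)
  ls
}

# expand unit-level eta to haul rows
.map_units <- function(eta, st) {
  if (isTRUE(st$identity_map)) eta else eta[st$unit, , drop = FALSE]
}

# discrete draw of the spatial range per factor from prior x GP likelihood
.update_alpha <- function(ls, st) {
  G <- length(st$alpha_grid)
  for (h in seq_len(ls$k)) {
    if (st$mode == "full") {
      eta_h <- ls$eta[, h]
      ll <- vapply(seq_len(G), function(g) {
        if (st$alpha_grid[g] <= 0) return(-0.5 * sum(eta_h^2))
        if (g == ls$alpha_idx[h] && !is.null(ls$coef[[h]])) {
          wv <- ls$coef[[h]]
        } else {
          wv <- crossprod(st$eig[[g]]$U, eta_h)[, 1]
        }
        -0.5 * (sum(log(st$eig[[g]]$d)) + sum(wv^2 / st$eig[[g]]$d))
      }, 0)
    } else {
      es <- ls$eta_knots[, h]
      ll <- vapply(seq_len(G), function(g) {
        if (st$alpha_grid[g] <= 0) return(if (all(es == 0)) 0 else -Inf)
        pp <- st$pp[[g]]
        v <- backsolve(pp$cholKmm, es, transpose = TRUE)
        -0.5 * (pp$logdetKmm + sum(v^2))
      }, 0)
    }
    lw <- ll + log(st$alpha_prior)
    w <- exp(lw - max(lw))
    new_idx <- sample.int(G, 1L, prob = w)
    if (new_idx != ls$alpha_idx[h]) {
      ls$alpha_idx[h] <- new_idx
      ls$coef[h] <- list(NULL)
    }
  }
  ls
}

# joint conjugate draw of all levels' loadings, species by species, under the
# multiplicative-gamma shrinkage prior
.update_lambda <- function(levels_state, levels_struct, E, w) {
  ks <- vapply(levels_state, function(l) as.integer(l$k), 0L)
  if (sum(ks) == 0) return(levels_state)
  Wm <- do.call(cbind, lapply(seq_along(levels_state), function(i)
    .map_units(levels_state[[i]]$eta, levels_struct[[i]])))
  WtW <- crossprod(Wm)
  rhs <- crossprod(Wm, E)                           # ktot x p
  prior_prec <- do.call(rbind, lapply(levels_state, function(l)
    if (l$k > 0) l$phi * cumprod(l$delta) else NULL))
  p <- ncol(E)
  Lam <- matrix(0, sum(ks), p)
  for (j in seq_len(p)) {
    prec <- WtW * w[j] + diag(prior_prec[, j], sum(ks))
    ch <- .safe_chol(prec, "loading precision")
    mu <- backsolve(ch, backsolve(ch, rhs[, j] * w[j], transpose = TRUE))
    Lam[, j] <- mu + backsolve(ch, stats::rnorm(sum(ks)))
  }
  ofs <- 0L
  for (i in seq_along(levels_state)) {
    if (ks[i] > 0) {
      levels_state[[i]]$Lambda <- Lam[ofs + seq_len(ks[i]), , drop = FALSE]
      ofs <- ofs + ks[i]
    }
  }
  levels_state
}

# multiplicative-gamma shrinkage hyperparameters (per level)
.update_shrinkage <- function(ls, shrink) {
  k <- ls$k
  if (k == 0) return(ls)
  p <- ncol(ls$Lambda)
  tau <- cumprod(ls$delta)
  L2 <- ls$Lambda^2
  ls$phi <- matrix(stats::rgamma(k * p, shape = (shrink$nu + 1) / 2,
                                 rate = (shrink$nu + tau * L2) / 2), k, p)
  phiL2 <- rowSums(ls$phi * L2)                     # per factor
  for (m in seq_len(k)) {
    tau_m <- cumprod(ls$delta) / ls$delta[m]
    shape <- (if (m == 1) shrink$a1 else shrink$a2) + p * (k - m + 1) / 2
    rate <- (if (m == 1) shrink$b1 else shrink$b2) +
      0.5 * sum(tau_m[m:k] * phiL2[m:k])
    ls$delta[m] <- stats::rgamma(1, shape = shape, rate = rate)
  }
  ls
}

# --- the sampler ------------------------------------------------------------

# Y: n x p matrix; probit: 0/1, gaussian: scaled log abundance with NA at
# absences. levels_struct: list of level structures. Returns an
# `hjsdm_post` with draws pooled over chains.
.gibbs_sampler <- function(Y, family = c("probit", "gaussian"),
                           X, Tm, C, levels_struct, control,
                           seed_offset = 0L, verbose = FALSE) {
  family <- match.arg(family)
  n <- nrow(Y); p <- ncol(Y); K <- ncol(X); q <- ncol(Tm)
  if (qr(X)$rank < K) {
    cors <- abs(stats::cor(X[, -1]))
    diag(cors) <- 0
    worst <- which(cors == max(cors), arr.ind = TRUE)[1, ]
    stop("design matrix is rank deficient (most collinear columns: ",
         paste(colnames(X)[-1][worst], collapse = ", "), ")")
  }
  .check_psd(C, "phylogenetic correlation C")
  eC <- eigen((C + t(C)) / 2, symmetric = TRUE)
  EC <- eC$vectors; lamC <- pmax(eC$values, 0)
  XtX <- crossprod(X)
  obs_mask <- !is.na(Y)
  if (family == "probit" && !all(obs_mask))
    stop("probit responses cannot be missing")
  Yg <- Y; Yg[!obs_mask] <- 0
  fx <- control$fixed
  rho_grid <- control$rho_grid
  rho_prior <- control$rho_prior
  n_keep <- (control$n_iter - control$n_burnin) %/% control$thin
  stopifnot(n_keep >= 1)

  draws <- vector("list", control$n_chains)
  for (chain in seq_len(control$n_chains)) {
    set.seed((control$seed + seed_offset + 7919L * chain) %% .Machine$integer.max)
    # state: crude ridge start for B from a signed/zero-filled response
    z0 <- if (family == "probit") 2 * Yg - 1 else Yg
    B <- solve(XtX + diag(K), crossprod(X, z0))
    Gamma <- matrix(0, q, K)
    V <- if (!is.null(fx$V)) fx$V else diag(K)
    rho <- if (!is.null(fx$rho)) fx$rho else rho_grid[1]
    sigma <- if (!is.null(fx$sigma)) fx$sigma else rep(1, p)
    if (family == "probit") sigma <- rep(1, p)
    lstate <- lapply(levels_struct, function(st) {
      k <- st$k_factors
      list(k = k,
           eta = matrix(0, st$nu, k),
           eta_knots = if (st$type == "spatial" && st$mode == "predictive")
             matrix(0, nrow(st$knots), k) else NULL,
           Lambda = matrix(stats::rnorm(k * p, 0, 0.05), k, p),
           alpha_idx = rep(1L, k),
           coef = vector("list", k),
           phi = matrix(1, k, p), delta = rep(1, k))
    })
    keep <- 0L
    st_B <- array(NA_real_, c(K, p, n_keep))
    st_G <- array(NA_real_, c(q, K, n_keep))
    st_V <- array(NA_real_, c(K, K, n_keep))
    st_rho <- numeric(n_keep)
    st_sig <- matrix(NA_real_, p, n_keep)
    st_lev <- lapply(levels_struct, function(st) list(
      Lambda = array(NA_real_, c(st$k_factors, p, n_keep)),
      eta = array(NA_real_, c(st$nu, st$k_factors, n_keep)),
      eta_knots = if (st$type == "spatial" && st$mode == "predictive")
        array(NA_real_, c(nrow(st$knots), st$k_factors, n_keep)) else NULL,
      alpha = if (st$type == "spatial")
        matrix(NA_real_, st$k_factors, n_keep) else NULL))

    for (iter in seq_len(control$n_iter)) {
      FC <- .factor_contribution(lstate, levels_struct, n, p)
      L <- X %*% B + FC
      z <- if (family == "probit") .update_z_probit(Yg, L)
           else .update_z_gaussian(Yg, L, sigma, obs_mask)
      w <- 1 / sigma^2
      bg <- .update_beta_gamma(z - FC, X, XtX, Tm, EC, lamC, rho, V, w,
                               control$gamma_var, fixed_Gamma = fx$Gamma)
      B <- bg$B; Gamma <- bg$Gamma
      if (is.null(fx$V))
        V <- .update_V(B, Gamma, Tm, EC, lamC, rho, control$V_scale,
                       control$V_df)
      if (is.null(fx$rho))
        rho <- .update_rho(B, Gamma, Tm, EC, lamC, V, rho_grid, rho_prior)
      E <- z - X %*% B
      if (length(lstate)) {
        contribs <- lapply(seq_along(lstate), function(i)
          if (lstate[[i]]$k > 0)
            .map_units(lstate[[i]]$eta, levels_struct[[i]]) %*% lstate[[i]]$Lambda
          else matrix(0, n, p))
        upd_alpha <- (iter %% control$alpha_every) == 0L
        for (i in seq_along(lstate)) {
          Ehat <- E - Reduce(`+`, contribs[-i], matrix(0, n, p))
          lstate[[i]] <- .update_level_factors(lstate[[i]], levels_struct[[i]],
                                               Ehat, w, upd_alpha)
          contribs[[i]] <- if (lstate[[i]]$k > 0)
            .map_units(lstate[[i]]$eta, levels_struct[[i]]) %*% lstate[[i]]$Lambda
          else matrix(0, n, p)
        }
        lstate <- .update_lambda(lstate, levels_struct, E, w)
        for (i in seq_along(lstate))
          lstate[[i]] <- .update_shrinkage(lstate[[i]], control$shrink)
      }
      if (family == "gaussian" && is.null(fx$sigma)) {
        FC <- .factor_contribution(lstate, levels_struct, n, p)
        sigma <- .update_sigma(z - X %*% B - FC, control$sigma_prior[1],
                               control$sigma_prior[2])
      }
      if (iter > control$n_burnin &&
          (iter - control$n_burnin) %% control$thin == 0L) {
        keep <- keep + 1L
        st_B[, , keep] <- B
        st_G[, , keep] <- Gamma
        st_V[, , keep] <- V
        st_rho[keep] <- rho
        st_sig[, keep] <- sigma
        for (i in seq_along(lstate)) {
          st_lev[[i]]$Lambda[, , keep] <- lstate[[i]]$Lambda
          st_lev[[i]]$eta[, , keep] <- lstate[[i]]$eta
          if (!is.null(st_lev[[i]]$eta_knots))
            st_lev[[i]]$eta_knots[, , keep] <- lstate[[i]]$eta_knots
          if (!is.null(st_lev[[i]]$alpha))
            st_lev[[i]]$alpha[, keep] <-
              levels_struct[[i]]$alpha_grid[lstate[[i]]$alpha_idx]
        }
      }
      if (verbose && iter %% 500 == 0)
        message(family, " chain ", chain, " iteration ", iter, "/",
                control$n_iter)
    }
    draws[[chain]] <- list(B = st_B, Gamma = st_G, V = st_V, rho = st_rho,
                           sigma = st_sig, levels = st_lev)
  }
  .bind_chains(draws, levels_struct, control, family,
               dimnames_B = list(colnames(X), colnames(Y)),
               dimnames_G = list(colnames(Tm), colnames(X)))
}

.factor_contribution <- function(lstate, levels_struct, n, p) {
  if (!length(lstate)) return(matrix(0, n, p))
  Reduce(`+`, lapply(seq_along(lstate), function(i)
    if (lstate[[i]]$k > 0)
      .map_units(lstate[[i]]$eta, levels_struct[[i]]) %*% lstate[[i]]$Lambda
    else matrix(0, n, p)))
}

.bind_chains <- function(draws, levels_struct, control, family,
                         dimnames_B, dimnames_G) {
  nc <- length(draws)
  nk <- length(draws[[1]]$rho)
  abind3 <- function(lst) array(unlist(lst), dim = c(dim(lst[[1]])[1:2], nc * nk))
  post <- list(
    family = family,
    B = abind3(lapply(draws, `[[`, "B")),
    Gamma = abind3(lapply(draws, `[[`, "Gamma")),
    V = abind3(lapply(draws, `[[`, "V")),
    rho = unlist(lapply(draws, `[[`, "rho")),
    sigma = do.call(cbind, lapply(draws, `[[`, "sigma")),
    chain = rep(seq_len(nc), each = nk),
    n_draws = nc * nk,
    levels = lapply(seq_along(levels_struct), function(i) {
      st <- levels_struct[[i]]
      out <- list(name = st$name, type = st$type,
                  k_factors = st$k_factors, nu = st$nu,
                  Lambda = abind3(lapply(draws, function(d) d$levels[[i]]$Lambda)),
                  eta = abind3(lapply(draws, function(d) d$levels[[i]]$eta)))
      if (st$type == "spatial") {
        out$alpha <- do.call(cbind, lapply(draws, function(d) d$levels[[i]]$alpha))
        out$alpha_grid <- st$alpha_grid
        out$mode <- st$mode
        if (st$mode == "predictive") {
          out$knots <- st$knots
          out$eta_knots <- abind3(lapply(draws, function(d) d$levels[[i]]$eta_knots))
        }
      }
      out
    }),
    control = control)
  dimnames(post$B) <- c(dimnames_B, list(NULL))
  dimnames(post$Gamma) <- c(dimnames_G, list(NULL))
  names(post$levels) <- vapply(levels_struct, `[[`, "", "name")
  class(post) <- "hjsdm_post"
  post
}
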