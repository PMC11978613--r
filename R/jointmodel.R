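# Marginal maximum-likelihood estimation of the K-marker joint
# longitudinal-survival model.
#
# Likelihood structure.  With intercept-only random effects b_i ~
# N(0, Sigma_b), the subject contribution is
#
#   L_i = int [ prod_j N_K(y_ij; X_ij beta + A_j b, Sigma_eps[obs_j]) ]
#             * lambda_i(T_i)^delta_i exp(-Lambda_i(entry -> T_i))
#             * phi_K(b; 0, Sigma_b) db
#
# with lambda_i(u) = exp(s0(u)'omega + w_i'gamma + sum_k alpha_k
# mu_ik(u)) and mu_ik(u) = x_ik(u)'beta_k + b_ik.  The longitudinal
# factor times the prior is Gaussian in b, so it collapses analytically
# to a normalizing constant times N(b; m_i, V_i).  Because the random
# effects are intercepts, the hazard depends on b only through the
# scalar a = alpha'b, giving
#
#   L_i = C_i * int exp(delta_i a - e^a Lambda0_i) N(a; alpha'm_i,
#                                                    alpha'V_i alpha) da
#         * exp(delta_i eta_i(T_i))
#
# where Lambda0_i integrates exp(eta_i(u)) (the fixed part of the log
# hazard) over (entry, T_i] by Gauss-Legendre quadrature.  The
# remaining one-dimensional integral is evaluated by adaptive
# Gauss-Hermite quadrature centered and scaled at the mode of its
# integrand.  This reduction is exact for any number of markers.

# ---------------------------------------------------------------------
# data preparation

jm_survival_covariates <- function(specs) {
  if ("bmi" %in% vapply(specs, `[[`, "", "name")) c("hrt", "fh")
  else c("bmi_baseline", "hrt", "fh")
}

jm_prepare <- function(subjects, visits, specs, marker_basis, hazard_basis,
                       survival_covariates, gl_nodes = 15L) {
  n <- nrow(subjects)
  ord <- order(match(visits$id, subjects$id), visits$age)
  visits <- visits[ord, , drop = FALSE]
  vis_subj <- match(visits$id, subjects$id)
  if (anyNA(vis_subj))
    stop("visits reference unknown subject ids", call. = FALSE)
  if (any(tabulate(vis_subj, n) == 0L))
    stop("every subject must have at least one visit", call. = FALSE)

  K <- length(specs)
  markers <- vapply(specs, `[[`, "", "name")
  designs <- lapply(specs, function(sp)
    build_marker_design(visits, subjects, sp, marker_basis))
  obs <- vapply(designs, `[[`, logical(nrow(visits)), "observed")
  obs <- matrix(obs, ncol = K, dimnames = list(NULL, markers))

  delta <- as.numeric(subjects$event)
  entry <- as.numeric(subjects$entry_age)
  exit <- as.numeric(subjects$exit_age)

  W <- covariate_design(subjects, survival_covariates)
  S_T <- cbind(1, eval_basis(hazard_basis, exit))
  X_T <- lapply(specs, function(sp) {
    Z <- covariate_design(subjects, sp$covariates)
    cbind(1, eval_basis(marker_basis, exit), Z)
  })

  gl <- gl_rule01(gl_nodes)
  len <- exit - entry
  ages_G <- outer(len, gl$x) + entry            # n x Q
  wts_G <- outer(len, gl$w)                     # n x Q
  agev <- as.vector(ages_G)
  S_G <- cbind(1, eval_basis(hazard_basis, agev))
  X_G <- lapply(specs, function(sp) {
    Z <- covariate_design(subjects, sp$covariates)
    cbind(1, eval_basis(marker_basis, agev),
          Z[rep(seq_len(n), times = gl_nodes), , drop = FALSE])
  })

  # per-visit missingness patterns and per-subject pattern counts
  pat_code <- as.integer(obs %*% 2L^(seq_len(K) - 1L))
  pats <- sort(unique(pat_code))
  pat_idx <- match(pat_code, pats)
  counts <- matrix(0L, n, length(pats))
  for (p in seq_along(pats)) {
    tab <- tabulate(vis_subj[pat_idx == p], nbins = n)
    counts[, p] <- tab
  }
  gid <- match(apply(counts, 1L, paste, collapse = ","),
               unique(apply(counts, 1L, paste, collapse = ",")))

  list(n = n, K = K, markers = markers, specs = specs,
       ids = subjects$id, delta = delta, entry = entry, exit = exit,
       y = lapply(designs, `[[`, "y"), X = lapply(designs, `[[`, "X"),
       obs = obs, vis_subj = vis_subj,
       W = W, S_T = S_T, X_T = X_T,
       wts_G = wts_G, S_G = S_G, X_G = X_G, gl_nodes = gl_nodes,
       pats = pats, pat_idx = pat_idx, counts = counts, gid = gid,
       marker_basis = marker_basis, hazard_basis = hazard_basis,
       survival_covariates = survival_covariates)
}

# ---------------------------------------------------------------------
# likelihood core

# 1-D adaptive Gauss-Hermite evaluation of
#   log int exp(delta*a - e^a * Lam0) N(a; mu, sig2) da
# vectorized over subjects; degenerate sig2 handled in closed form.
# Optionally returns the derivatives of log I with respect to mu
# (u1), sig2 (u2) and Lam0 (u3) from the posterior moments of a.
jm_frailty_moments <- function(delta, Lam0, mu, sig2, gh,
                               want_grad = FALSE) {
  n <- length(mu)
  out <- numeric(n)
  u1 <- numeric(n); u2 <- numeric(n); u3 <- numeric(n)
  deg <- sig2 < 1e-12
  if (any(deg)) {
    eL <- exp(pmin(mu[deg], 690))
    out[deg] <- delta[deg] * mu[deg] - eL * Lam0[deg]
    if (want_grad) {
      g1 <- delta[deg] - eL * Lam0[deg]
      u1[deg] <- g1
      u2[deg] <- 0.5 * (g1^2 - eL * Lam0[deg])
      u3[deg] <- -eL
    }
  }
  if (all(deg))
    return(list(logI = out, u1 = u1, u2 = u2, u3 = u3))

  i <- which(!deg)
  d <- delta[i]; L0 <- Lam0[i]; m0 <- mu[i]; s2 <- sig2[i]
  logL0 <- log(L0)                     # -Inf when Lam0 = 0 is fine
  a <- m0
  for (it in seq_len(60L)) {
    eL <- exp(pmin(a + logL0, 690))
    g1 <- d - eL - (a - m0) / s2
    g2 <- -eL - 1 / s2
    step <- g1 / g2
    step[!is.finite(step)] <- 0
    step <- pmin(pmax(step, -5), 5)    # safeguard huge Newton moves
    a <- a - step
    if (max(abs(step)) < 1e-12) break
  }
  eL <- exp(pmin(a + logL0, 690))
  shat <- 1 / sqrt(eL + 1 / s2)        # curvature scale at the mode
  z <- gh$x; w <- gh$w
  A <- outer(shat * sqrt(2), z) + a    # n_i x Q nodes
  H <- d * A - exp(pmin(A + logL0, 690)) - (A - m0)^2 / (2 * s2)
  LW <- sweep(H, 2L, log(w) + z^2, `+`)
  mx <- apply(LW, 1L, max)
  E <- exp(LW - mx)
  tot <- rowSums(E)
  out[i] <- log(sqrt(2) * shat) - 0.5 * log(2 * pi * s2) + mx + log(tot)
  if (want_grad) {
    P <- E / tot                        # posterior weights over nodes
    E1 <- rowSums(P * A)
    Ec2 <- rowSums(P * (A - m0)^2)
    Eea <- rowSums(P * exp(pmin(A, 690)))
    u1[i] <- (E1 - m0) / s2
    u2[i] <- Ec2 / (2 * s2^2) - 1 / (2 * s2)
    u3[i] <- -Eea
  }
  list(logI = out, u1 = u1, u2 = u2, u3 = u3)
}

# Forward evaluation of all per-subject likelihood quantities; when
# `want_grad` the analytic gradient with respect to every natural
# parameter block is accumulated as well (chain rule through the
# conjugate Gaussian collapse and the posterior moments of a =
# alpha'b under the Gauss-Hermite rule).
jm_eval <- function(beta, Sigma_b, Sigma_eps, omega, gamma, alpha,
                    prep, gh_nodes = 7L, survival = TRUE,
                    want_grad = FALSE) {
  n <- prep$n; K <- prep$K
  m <- length(prep$y[[1L]])
  fail <- list(ll = rep(NA_real_, n))
  if (any(!is.finite(unlist(beta))) || any(!is.finite(Sigma_b)) ||
      any(!is.finite(Sigma_eps)) || any(!is.finite(omega)) ||
      any(!is.finite(gamma)) || any(!is.finite(alpha)))
    return(fail)

  R <- matrix(NA_real_, m, K)
  for (k in seq_len(K))
    R[, k] <- prep$y[[k]] - drop(prep$X[[k]] %*% beta[[k]])

  vis_ll <- numeric(m)
  Scontrib <- matrix(0, m, K)
  M_embed <- vector("list", length(prep$pats))
  Sinv_p <- vector("list", length(prep$pats))
  O_p <- vector("list", length(prep$pats))
  for (p in seq_along(prep$pats)) {
    O <- which(bitwAnd(prep$pats[p], 2L^(seq_len(K) - 1L)) > 0L)
    O_p[[p]] <- O
    rows <- which(prep$pat_idx == p)
    if (!length(O)) { M_embed[[p]] <- matrix(0, K, K); next }
    Sp <- Sigma_eps[O, O, drop = FALSE]
    ch <- tryCatch(chol(Sp), error = function(e) NULL)
    if (is.null(ch)) return(fail)
    Sinv <- chol2inv(ch)
    logdet <- 2 * sum(log(diag(ch)))
    Rp <- R[rows, O, drop = FALSE]
    Qp <- Rp %*% Sinv
    vis_ll[rows] <- -0.5 * (length(O) * log(2 * pi) + logdet +
                            rowSums(Qp * Rp))
    Scontrib[rows, O] <- Qp
    Mk <- matrix(0, K, K); Mk[O, O] <- Sinv
    M_embed[[p]] <- Mk
    Sinv_p[[p]] <- Sinv
  }
  grp <- factor(prep$vis_subj, levels = seq_len(n))
  vis_ll_i <- drop(rowsum(vis_ll, grp))
  s_i <- rowsum(Scontrib, grp)
  if (max(abs(s_i)) > 1e8) return(fail)  # cancellation-unsafe region

  chb <- tryCatch(chol(Sigma_b), error = function(e) NULL)
  if (is.null(chb)) return(fail)
  Sb_inv <- chol2inv(chb)
  logdet_Sb <- 2 * sum(log(diag(chb)))

  quad_i <- numeric(n); logdetV_i <- numeric(n)
  mu_a <- numeric(n); sig2_a <- numeric(n)
  m_all <- matrix(0, n, K)            # posterior mean of b
  v_all <- matrix(0, n, K)            # V alpha, per subject
  V_g <- vector("list", max(prep$gid))
  for (g in unique(prep$gid)) {
    sub <- which(prep$gid == g)
    Pg <- Sb_inv
    for (p in seq_along(prep$pats))
      Pg <- Pg + prep$counts[sub[1L], p] * M_embed[[p]]
    chp <- tryCatch(chol(Pg), error = function(e) NULL)
    if (is.null(chp)) return(fail)
    Vg <- chol2inv(chp)
    V_g[[g]] <- Vg
    logdetV_i[sub] <- -2 * sum(log(diag(chp)))
    Ssub <- s_i[sub, , drop = FALSE]
    SV <- Ssub %*% Vg
    m_all[sub, ] <- SV
    quad_i[sub] <- rowSums(SV * Ssub)
    mu_a[sub] <- drop(SV %*% alpha)
    sig2_a[sub] <- drop(crossprod(alpha, Vg %*% alpha))
    v_all[sub, ] <- matrix(drop(Vg %*% alpha), length(sub), K, byrow = TRUE)
  }

  if (any(!is.finite(quad_i)) || any(!is.finite(mu_a)) ||
      any(!is.finite(sig2_a)) || any(sig2_a < 0))
    return(fail)
  ll <- vis_ll_i + 0.5 * quad_i + 0.5 * logdetV_i - 0.5 * logdet_Sb

  if (survival) {
    Wg <- drop(prep$W %*% gamma)
    eta_T <- drop(prep$S_T %*% omega) + Wg
    eta_Gv <- drop(prep$S_G %*% omega)
    mu_fix_T <- vector("list", K); mu_fix_G <- vector("list", K)
    for (k in seq_len(K)) {
      mu_fix_T[[k]] <- drop(prep$X_T[[k]] %*% beta[[k]])
      mu_fix_G[[k]] <- drop(prep$X_G[[k]] %*% beta[[k]])
      eta_T <- eta_T + alpha[k] * mu_fix_T[[k]]
      eta_Gv <- eta_Gv + alpha[k] * mu_fix_G[[k]]
    }
    if (any(!is.finite(eta_T)) || any(!is.finite(eta_Gv))) return(fail)
    ww <- prep$wts_G * exp(pmin(matrix(eta_Gv, n, prep$gl_nodes) + Wg, 690))
    Lam0 <- rowSums(ww)
    fr <- jm_frailty_moments(prep$delta, Lam0, mu_a, sig2_a,
                             gh_rule(gh_nodes), want_grad)
    ll <- ll + prep$delta * eta_T + fr$logI
  }

  if (!want_grad) return(list(ll = ll))

  # ----- gradient accumulation (natural parameter blocks) -----
  u1 <- if (survival) fr$u1 else numeric(n)   # dlogI/dmu_a
  u2 <- if (survival) fr$u2 else numeric(n)   # dlogI/dsig2_a
  u3 <- if (survival) fr$u3 else numeric(n)   # dlogI/dLam0

  # beta: longitudinal part via pattern-wise GLS residuals around the
  # posterior mean, association part via u1, survival fixed part via
  # delta and u3
  Dif <- R - m_all[prep$vis_subj, , drop = FALSE]
  Wrow <- v_all[prep$vis_subj, , drop = FALSE] * u1[prep$vis_subj]
  Targ <- matrix(0, m, K)
  for (p in seq_along(prep$pats)) {
    O <- O_p[[p]]
    if (!length(O)) next
    rows <- which(prep$pat_idx == p)
    Targ[rows, O] <- (Dif[rows, O, drop = FALSE] -
                      Wrow[rows, O, drop = FALSE]) %*% Sinv_p[[p]]
  }
  g_beta <- vector("list", K)
  if (survival) {
    nw <- as.vector(ww * u3)            # length n*Q, u3 recycled by column
    for (k in seq_len(K)) {
      g_beta[[k]] <- drop(crossprod(prep$X[[k]][prep$obs[, k], , drop = FALSE],
                                    Targ[prep$obs[, k], k])) +
        alpha[k] * (drop(crossprod(prep$X_T[[k]], prep$delta)) +
                    drop(crossprod(prep$X_G[[k]], nw)))
    }
    g_omega <- drop(crossprod(prep$S_T, prep$delta)) +
      drop(crossprod(prep$S_G, nw))
    g_gamma <- drop(crossprod(prep$W, prep$delta + u3 * Lam0))
    g_alpha <- numeric(K)
    for (k in seq_len(K)) {
      g_alpha[k] <- sum(prep$delta * mu_fix_T[[k]]) +
        sum(nw * mu_fix_G[[k]]) +
        sum(u1 * m_all[, k]) + 2 * sum(u2 * v_all[, k])
    }
  } else {
    for (k in seq_len(K))
      g_beta[[k]] <- drop(crossprod(prep$X[[k]][prep$obs[, k], , drop = FALSE],
                                    Targ[prep$obs[, k], k]))
    g_omega <- numeric(length(omega))
    g_gamma <- numeric(length(gamma))
    g_alpha <- numeric(K)
  }

  # covariance blocks: collect per-subject T_i = 1/2 m m' + 1/2 V +
  # u1 sym(v m') + u2 v v', aggregated per posterior-precision group
  G_b <- matrix(0, K, K)
  Tsum_g <- vector("list", max(prep$gid))
  for (g in unique(prep$gid)) {
    sub <- which(prep$gid == g)
    Ms <- m_all[sub, , drop = FALSE]
    v <- v_all[sub[1L], ]
    mm <- crossprod(Ms)
    u1m <- drop(crossprod(m_all[sub, , drop = FALSE], u1[sub]))
    vm <- tcrossprod(v, u1m)
    Tg <- 0.5 * mm + 0.5 * length(sub) * V_g[[g]] +
      0.5 * (vm + t(vm)) + sum(u2[sub]) * tcrossprod(v)
    Tsum_g[[g]] <- Tg
    G_b <- G_b + Tg
  }
  G_b <- Sb_inv %*% G_b %*% Sb_inv - 0.5 * n * Sb_inv

  # Sigma_eps: (a) per-visit Gaussian density term, (b) the ds path
  # contracted with (m + u1 v), (c) the dP path reusing T_i
  G_e <- matrix(0, K, K)
  Wvec <- m_all + v_all * u1          # n x K, per subject w = m + u1 v
  for (p in seq_along(prep$pats)) {
    O <- O_p[[p]]
    if (!length(O)) next
    rows <- which(prep$pat_idx == p)
    Sinv <- Sinv_p[[p]]
    Rp <- R[rows, O, drop = FALSE]
    Qp <- Rp %*% Sinv                  # Sinv r_j
    # (a) 1/2 (Sinv r r' Sinv - count Sinv)
    Ga <- 0.5 * (crossprod(Qp) - length(rows) * Sinv)
    # (b) - Sinv r_j (w_O)' Sinv summed over visits (w = m + u1 v)
    Wp <- Wvec[prep$vis_subj[rows], O, drop = FALSE] %*% Sinv
    Gb2 <- -crossprod(Qp, Wp)
    Gb2 <- 0.5 * (Gb2 + t(Gb2))        # symmetric contraction of dSigma
    # (c) dP path: per-visit T_i weighted by pattern counts
    Tacc <- matrix(0, K, K)
    for (g in unique(prep$gid)) {
      c_gp <- prep$counts[which(prep$gid == g)[1L], p]
      if (c_gp > 0) Tacc <- Tacc + c_gp * Tsum_g[[g]]
    }
    Gc <- Sinv %*% Tacc[O, O, drop = FALSE] %*% Sinv
    G_e[O, O] <- G_e[O, O] + Ga + Gb2 + Gc
  }

  list(ll = ll, g_beta = g_beta, G_b = G_b, G_e = G_e,
       g_omega = g_omega, g_gamma = g_gamma, g_alpha = g_alpha)
}

# compatibility wrapper returning only the per-subject log-likelihoods
jm_loglik_vec <- function(beta, Sigma_b, Sigma_eps, omega, gamma, alpha,
                          prep, gh_nodes = 7L, survival = TRUE) {
  jm_eval(beta, Sigma_b, Sigma_eps, omega, gamma, alpha, prep,
          gh_nodes = gh_nodes, survival = survival)$ll
}

# chain rule from a symmetric-matrix gradient (dl = tr(G dSigma)) to
# the packed log-Cholesky parameters
chol_chain <- function(G, L) {
  GL <- (G + t(G)) %*% L
  idx <- which(lower.tri(L, diag = TRUE), arr.ind = TRUE)
  g <- GL[idx]
  on_diag <- idx[, 1] == idx[, 2]
  g[on_diag] <- g[on_diag] * diag(L)
  g
}

# negative log-likelihood and gradient in the packed parameterization,
# with a one-slot cache so optim's fn/gr pairs cost one evaluation
jm_objective <- function(prep, gh_nodes, survival = TRUE) {
  cache_theta <- NULL; cache <- NULL
  evaluate <- function(theta) {
    if (!is.null(cache_theta) && identical(theta, cache_theta))
      return(cache)
    if (any(!is.finite(theta)) || any(abs(theta) > 50)) {
      # far outside any plausible region: reject before numerics degrade
      cache_theta <<- theta; cache <<- list(value = 1e10, grad = NULL)
      return(cache)
    }
    pl <- jm_unpack(theta, prep)
    K <- prep$K
    q <- n_chol_par(K)
    pos_sb <- sum(vapply(pl$beta, length, 1L))
    ev <- jm_eval(pl$beta, pl$Sigma_b, pl$Sigma_eps, pl$omega, pl$gamma,
                  pl$alpha, prep, gh_nodes = gh_nodes,
                  survival = survival, want_grad = TRUE)
    if (anyNA(ev$ll)) {
      res <- list(value = 1e10, grad = NULL)
    } else {
      L_b <- theta_to_chol(theta[pos_sb + seq_len(q)], K)
      L_e <- theta_to_chol(theta[pos_sb + q + seq_len(q)], K)
      grad <- c(unlist(ev$g_beta, use.names = FALSE),
                chol_chain(ev$G_b, L_b), chol_chain(ev$G_e, L_e),
                ev$g_omega, ev$g_gamma, ev$g_alpha)
      res <- list(value = -sum(ev$ll), grad = -grad)
    }
    cache_theta <<- theta; cache <<- res
    res
  }
  list(fn = function(theta) evaluate(theta)$value,
       gr = function(theta) {
         g <- evaluate(theta)$grad
         if (is.null(g)) rep(0, length(theta)) else g
       })
}

# survival-only partial problem used for starting values (alpha = 0,
# random effects irrelevant)
jm_surv_loglik <- function(omega, gamma, prep) {
  Wg <- drop(prep$W %*% gamma)
  eta_T <- drop(prep$S_T %*% omega) + Wg
  Lam0 <- rowSums(prep$wts_G *
                  exp(matrix(drop(prep$S_G %*% omega), prep$n,
                             prep$gl_nodes) + Wg))
  sum(prep$delta * eta_T - Lam0)
}

# ---------------------------------------------------------------------
# public single-subject operations

subject_row <- function(subjects, id) subjects[subjects$id == id, , drop = FALSE]

#' Subject-specific hazard under the joint model
#'
#' Evaluates lambda_i(age) = exp(s0(age)'omega + w_i'gamma +
#' sum_k alpha_k mu_ik(age)) for one subject at given random
#' intercepts.
#'
#' @param age numeric vector of ages.
#' @param subject one-row subject data.frame.
#' @param params a \code{\link{joint_params}}.
#' @param b_i named numeric vector of random intercepts (one per
#'   marker; defaults to zeros).
#' @return numeric vector of hazards.
#' @export
jm_hazard <- function(age, subject, params, b_i = NULL) {
  K <- length(params$specs)
  if (is.null(b_i)) b_i <- numeric(K)
  if (is.null(names(b_i))) names(b_i) <- names(params$beta)
  s0 <- cbind(1, eval_basis(params$hazard_basis, age))
  W <- covariate_design(subject, survival_covariate_set(params))
  W <- W[, names(params$gamma), drop = FALSE]
  lp <- drop(s0 %*% params$omega) + rep(drop(W %*% params$gamma),
                                        length(age))
  for (k in names(params$beta)) {
    mu_k <- marker_mean(age, subject, params$specs[[k]], params$beta[[k]],
                        b_i[[k]], params$marker_basis)
    lp <- lp + params$alpha[[k]] * mu_k
  }
  if (any(!is.finite(lp)))
    stop("non-finite hazard linear predictor", call. = FALSE)
  exp(lp)
}

survival_covariate_set <- function(params) {
  nm <- names(params$gamma)
  covs <- character(0)
  if ("bmi_baseline" %in% nm) covs <- c(covs, "bmi_baseline")
  if (any(grepl("^hrt", nm))) covs <- c(covs, "hrt")
  if (any(grepl("^fh", nm))) covs <- c(covs, "fh")
  covs
}

#' Cumulative hazard over an age interval
#'
#' Gauss-Legendre integral of \code{\link{jm_hazard}} over [a0, a1].
#'
#' @param a0,a1 interval endpoints (ages), a0 <= a1.
#' @param subject,params,b_i as in \code{\link{jm_hazard}}.
#' @param n_nodes quadrature node count.
#' @return the cumulative hazard (non-negative scalar).
#' @export
jm_cumulative_hazard <- function(a0, a1, subject, params, b_i = NULL,
                                 n_nodes = 30L) {
  if (a0 > a1) stop("`a0` must not exceed `a1`", call. = FALSE)
  if (a1 == a0) return(0)
  gl <- gl_rule01(n_nodes)
  u <- a0 + (a1 - a0) * gl$x
  (a1 - a0) * sum(gl$w * jm_hazard(u, subject, params, b_i))
}

#' Marginal log-likelihood contribution of one subject
#'
#' Integrates the product of the longitudinal Gaussian densities and the
#' survival factor over the random intercepts; visits where a marker is
#' unrecorded contribute the marginal density of the observed markers.
#' See the package vignette for the exact reduction used.
#'
#' @param subject one-row subject data.frame (entry/exit/event plus
#'   covariates).
#' @param visits this subject's visit rows.
#' @param params a \code{\link{joint_params}}.
#' @param gh_nodes Gauss-Hermite nodes for the association integral.
#' @param gl_nodes Gauss-Legendre nodes for the cumulative hazard.
#' @return scalar log-likelihood.
#' @export
subject_loglik <- function(subject, visits, params, gh_nodes = 7L,
                           gl_nodes = 30L) {
  prep <- jm_prepare(subject, visits, params$specs, params$marker_basis,
                     params$hazard_basis, survival_covariate_set(params),
                     gl_nodes = gl_nodes)
  gamma <- params$gamma[colnames(prep$W)]
  ll <- jm_loglik_vec(params$beta, params$Sigma_b, params$Sigma_eps,
                      params$omega, gamma, params$alpha, prep,
                      gh_nodes = gh_nodes)
  if (!is.finite(ll))
    stop("log-likelihood evaluation failed for subject ", subject$id,
         call. = FALSE)
  unname(ll)
}

# ---------------------------------------------------------------------
# parameter packing

jm_theta_skeleton <- function(prep) {
  K <- prep$K
  nm <- character(0)
  for (k in seq_len(K))
    nm <- c(nm, paste("beta", prep$markers[k],
                      colnames(prep$X[[k]]), sep = "."))
  tri <- which(lower.tri(diag(K), diag = TRUE), arr.ind = TRUE)
  nm <- c(nm, paste0("Sigma_b.L", tri[, 1], ".", tri[, 2]))
  nm <- c(nm, paste0("Sigma_eps.L", tri[, 1], ".", tri[, 2]))
  nm <- c(nm, paste0("omega", seq_len(ncol(prep$S_T))))
  nm <- c(nm, paste("gamma", colnames(prep$W), sep = "."))
  nm <- c(nm, paste("alpha", prep$markers, sep = "."))
  nm
}

jm_pack <- function(beta, Sigma_b, Sigma_eps, omega, gamma, alpha) {
  c(unlist(beta, use.names = FALSE),
    chol_to_theta(Sigma_b), chol_to_theta(Sigma_eps),
    omega, gamma, alpha)
}

jm_unpack <- function(theta, prep) {
  K <- prep$K
  pos <- 0L
  beta <- vector("list", K); names(beta) <- prep$markers
  for (k in seq_len(K)) {
    p_k <- ncol(prep$X[[k]])
    beta[[k]] <- theta[pos + seq_len(p_k)]; pos <- pos + p_k
  }
  q <- n_chol_par(K)
  Sigma_b <- theta_to_cov(theta[pos + seq_len(q)], K); pos <- pos + q
  Sigma_eps <- theta_to_cov(theta[pos + seq_len(q)], K); pos <- pos + q
  p_o <- ncol(prep$S_T)
  omega <- theta[pos + seq_len(p_o)]; pos <- pos + p_o
  p_w <- ncol(prep$W)
  gamma <- theta[pos + seq_len(p_w)]; pos <- pos + p_w
  alpha <- theta[pos + seq_len(K)]
  names(alpha) <- prep$markers
  list(beta = beta, Sigma_b = Sigma_b, Sigma_eps = Sigma_eps,
       omega = omega, gamma = setNames(gamma, colnames(prep$W)),
       alpha = alpha)
}

# ---------------------------------------------------------------------
# fitting

jm_default_options <- function() {
  list(gh_nodes = 7L, gl_nodes = 15L, maxit = 500L, reltol = 1e-13,
       grad_tol = 1e-3, se = TRUE, stage1_maxit = 300L,
       stage2_maxit = 300L)
}

# moment-based starting values for the longitudinal submodels
jm_start_longitudinal <- function(prep) {
  K <- prep$K
  beta <- vector("list", K); names(beta) <- prep$markers
  bhat <- matrix(0, prep$n, K)
  Sig_e <- diag(K); Sig_b <- diag(K)
  resid_list <- vector("list", K)
  grp <- factor(prep$vis_subj, levels = seq_len(prep$n))
  for (k in seq_len(K)) {
    ok <- prep$obs[, k]
    fitk <- lm.fit(prep$X[[k]][ok, , drop = FALSE], prep$y[[k]][ok])
    beta[[k]] <- fitk$coefficients
    beta[[k]][is.na(beta[[k]])] <- 0
    r <- rep(NA_real_, length(ok)); r[ok] <- fitk$residuals
    n_k <- drop(rowsum(as.numeric(ok), grp))
    rbar <- drop(rowsum(ifelse(ok, r, 0), grp)) / pmax(n_k, 1L)
    rbar[n_k == 0L] <- NA
    bhat[, k] <- rbar
    within <- r - rbar[prep$vis_subj]
    resid_list[[k]] <- within
    s2w <- var(within[ok & n_k[prep$vis_subj] > 1L], na.rm = TRUE)
    if (!is.finite(s2w) || s2w <= 0) s2w <- var(r[ok]) / 2
    s2b <- var(rbar, na.rm = TRUE) - s2w * mean(1 / pmax(n_k[n_k > 0], 1))
    Sig_e[k, k] <- s2w
    Sig_b[k, k] <- max(s2b, 0.05 * s2w)
  }
  Rw <- do.call(cbind, resid_list)
  Cw <- suppressWarnings(stats::cov(Rw, use = "pairwise.complete.obs"))
  Cb <- suppressWarnings(stats::cov(bhat, use = "pairwise.complete.obs"))
  for (i in seq_len(K)) for (j in seq_len(K)) {
    if (i == j) next
    rho_e <- if (is.finite(Cw[i, j])) Cw[i, j] / sqrt(Cw[i, i] * Cw[j, j]) else 0
    rho_b <- if (is.finite(Cb[i, j])) Cb[i, j] / sqrt(Cb[i, i] * Cb[j, j]) else 0
    rho_e <- max(min(rho_e, 0.95), -0.95)
    rho_b <- max(min(rho_b, 0.95), -0.95)
    Sig_e[i, j] <- rho_e * sqrt(Sig_e[i, i] * Sig_e[j, j])
    Sig_b[i, j] <- rho_b * sqrt(Sig_b[i, i] * Sig_b[j, j])
  }
  list(beta = beta, Sigma_b = nearest_pd(Sig_b), Sigma_eps = nearest_pd(Sig_e))
}

nearest_pd <- function(S, floor_frac = 1e-4) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  v <- pmax(e$values, floor_frac * max(e$values))
  e$vectors %*% (v * t(e$vectors))
}

#' Fit a multivariate joint longitudinal-survival model
#'
#' Maximizes the marginal likelihood of the bivariate (nondense, dense)
#' or trivariate (plus BMI) joint model by quasi-Newton optimization
#' with a two-stage start: the multivariate mixed model is first fitted
#' ignoring survival, the spline-baseline proportional-hazards submodel
#' is then fitted at association zero, and all parameters are finally
#' maximized jointly.  Covariance matrices are parameterized through
#' log-Cholesky factors, guaranteeing positive definiteness.  Left
#' truncation at the entry age is handled by integrating the hazard
#' over (entry, exit] only.
#'
#' @param cohort an \code{"mdjm_cohort"} or a list with \code{subjects}
#'   and \code{visits} tables.
#' @param model \code{"joint2"} (bivariate, baseline BMI in the
#'   survival submodel) or \code{"joint3"} (trivariate; the BMI
#'   trajectory replaces baseline BMI in the survival submodel).
#' @param specs marker specifications; defaults per \code{model}.
#' @param options list overriding \code{gh_nodes} (adaptive
#'   Gauss-Hermite nodes, default 7), \code{gl_nodes} (cumulative-hazard
#'   Gauss-Legendre nodes, default 15), \code{maxit}, \code{reltol},
#'   \code{grad_tol}, \code{se} (compute the covariance of the
#'   estimates via the numerically differenced Hessian; default TRUE).
#' @param fixed optional named numeric vector of packed parameters to
#'   hold fixed during optimization (names as in the fit's
#'   \code{estimates}).
#' @param init optional named list with starting values
#'   (\code{beta}, \code{Sigma_b}, \code{Sigma_eps}, \code{omega},
#'   \code{gamma}, \code{alpha}); missing pieces use the staged start.
#' @return object of class \code{"jm_fit"}: estimates (packed and as a
#'   \code{\link{joint_params}}), covariance matrix, log-likelihood,
#'   convergence flag and iteration count, hazard-ratio rows and the
#'   serialized knots and options.
#' @export
fit_joint_model <- function(cohort, model = c("joint2", "joint3"),
                            specs = NULL, options = list(),
                            fixed = NULL, init = NULL) {
  model <- match.arg(model)
  opts <- utils::modifyList(jm_default_options(), options)
  subjects <- cohort$subjects; visits <- cohort$visits
  if (is.null(specs)) specs <- default_marker_specs(model)
  if (length(specs) < 2L)
    stop("the joint model needs at least 2 markers", call. = FALSE)

  marker_basis <- spline_basis_from_data(visits$age, df = 5L)
  event_ages <- subjects$exit_age[subjects$event == 1]
  if (length(event_ages) < 8L)
    stop("too few events to place baseline-hazard knots", call. = FALSE)
  hazard_basis <- spline_basis_from_data(event_ages, df = 5L,
                                         clip = c(40, 95))
  surv_covs <- opts$survival_covariates %||% jm_survival_covariates(specs)
  prep <- jm_prepare(subjects, visits, specs, marker_basis, hazard_basis,
                     surv_covs, opts$gl_nodes)
  nm <- jm_theta_skeleton(prep)

  # stage 1: longitudinal-only fit
  start <- jm_start_longitudinal(prep)
  if (!is.null(init)) start <- utils::modifyList(start, init[intersect(
    names(init), c("beta", "Sigma_b", "Sigma_eps"))])
  th1 <- c(unlist(start$beta, use.names = FALSE),
           chol_to_theta(start$Sigma_b), chol_to_theta(start$Sigma_eps))
  n_long <- length(th1)
  obj_long <- jm_objective(prep, opts$gh_nodes, survival = FALSE)
  pad <- function(th) c(th, rep(0, length(nm) - n_long))
  o1 <- optim(th1, function(th) obj_long$fn(pad(th)),
              function(th) obj_long$gr(pad(th))[seq_len(n_long)],
              method = "BFGS",
              control = list(maxit = opts$stage1_maxit,
                             reltol = opts$reltol))

  # stage 2: survival submodel at alpha = 0
  p_o <- ncol(prep$S_T); p_w <- ncol(prep$W)
  persontime <- sum(prep$exit - prep$entry)
  th2 <- c(log(max(sum(prep$delta), 0.5) / persontime), rep(0, p_o - 1L),
           rep(0, p_w))
  surv_obj <- function(th) {
    ll <- jm_surv_loglik(th[seq_len(p_o)], th[p_o + seq_len(p_w)], prep)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  o2 <- optim(th2, surv_obj, method = "BFGS",
              control = list(maxit = opts$stage2_maxit, reltol = opts$reltol,
                             ndeps = rep(1e-5, length(th2))))

  theta0 <- c(o1$par, o2$par, rep(0, prep$K))
  names(theta0) <- nm
  if (!is.null(init)) {
    for (f in intersect(names(init), c("omega", "gamma", "alpha"))) {
      idx <- grep(paste0("^", f), nm)
      theta0[idx] <- init[[f]]
    }
  }

  free <- rep(TRUE, length(nm)); names(free) <- nm
  if (!is.null(fixed)) {
    if (!all(names(fixed) %in% nm))
      stop("unknown parameter in `fixed`: ",
           paste(setdiff(names(fixed), nm), collapse = ", "), call. = FALSE)
    theta0[names(fixed)] <- fixed
    free[names(fixed)] <- FALSE
  }

  obj <- jm_objective(prep, opts$gh_nodes, survival = TRUE)
  embed <- function(th_free) { th <- theta0; th[free] <- th_free; th }
  full_obj <- function(th_free) obj$fn(embed(th_free))
  full_gr <- function(th_free) obj$gr(embed(th_free))[free]
  o3 <- optim(theta0[free], full_obj, full_gr, method = "BFGS",
              control = list(maxit = opts$maxit, reltol = opts$reltol))
  # polish until the gradient criterion holds (BFGS restarts)
  for (r in seq_len(5L)) {
    if (max(abs(full_gr(o3$par))) < opts$grad_tol) break
    o3 <- optim(o3$par, full_obj, full_gr, method = "BFGS",
                control = list(maxit = opts$maxit, reltol = opts$reltol))
  }
  theta <- theta0; theta[free] <- o3$par
  loglik <- -o3$value
  gr <- full_gr(o3$par)
  converged <- o3$convergence == 0L && max(abs(gr)) < opts$grad_tol

  vc <- NULL
  if (isTRUE(opts$se)) {
    H <- stats::optimHess(o3$par, full_obj, full_gr,
                          control = list(ndeps = rep(1e-5, sum(free))))
    vc_free <- tryCatch(solve((H + t(H)) / 2), error = function(e) NULL)
    if (!is.null(vc_free)) {
      vc <- matrix(NA_real_, length(nm), length(nm), dimnames = list(nm, nm))
      vc[free, free] <- vc_free
    }
  }

  pl <- jm_unpack(theta, prep)
  params <- joint_params(pl$beta, pl$Sigma_b, pl$Sigma_eps, pl$omega,
                         pl$gamma, pl$alpha, specs, marker_basis,
                         hazard_basis, validate = FALSE)
  fit <- structure(list(estimates = theta, par = params, vcov = vc,
                        loglik = loglik, converged = converged,
                        n_iter = unname(o3$counts["function"]),
                        model = model, n = prep$n,
                        n_events = sum(prep$delta),
                        knots = list(marker = marker_basis,
                                     hazard = hazard_basis),
                        options = opts, free = free,
                        stage_loglik = c(longitudinal = -o1$value,
                                         survival = -o2$value),
                        grad_norm = max(abs(gr))),
                   class = "jm_fit")
  fit$hr_rows <- wald_inference(fit)
  fit
}

#' @export
print.jm_fit <- function(x, ...) {
  cat("Joint longitudinal-survival model (", x$model, "), n = ", x$n,
      ", events = ", x$n_events, "\n", sep = "")
  cat("log-likelihood:", format(x$loglik, digits = 8),
      if (!x$converged) " (NOT converged)" else "", "\n")
  cat("corr(b):", sprintf("%.3f", cov2corr_ij(x$par$Sigma_b, 1, 2)),
      " corr(eps):", sprintf("%.3f", cov2corr_ij(x$par$Sigma_eps, 1, 2)),
      "\n")
  if (!is.null(x$hr_rows)) {
    cat("Hazard ratios:\n")
    print(x$hr_rows, digits = 4, row.names = FALSE)
  }
  invisible(x)
}

# ---------------------------------------------------------------------
# Wald inference

#' Hazard-ratio table and Wald inference for a fitted model
#'
#' Exponentiates the survival-submodel coefficients (associations and
#' covariate effects) with normal-theory 95\% confidence intervals and
#' two-sided p-values.
#'
#' @param fit a \code{"jm_fit"} (or any object with \code{estimates}
#'   and \code{vcov} in the same layout).
#' @return data.frame with columns term, estimate, HR, ci_low, ci_high,
#'   p (HR columns are NA when no covariance is available).
#' @export
wald_inference <- function(fit) {
  terms <- grep("^(alpha|gamma)\\.", names(fit$estimates), value = TRUE)
  est <- fit$estimates[terms]
  se <- rep(NA_real_, length(terms))
  if (!is.null(fit$vcov))
    se <- sqrt(pmax(diag(fit$vcov)[terms], 0))
  z <- est / se
  data.frame(term = terms, estimate = unname(est),
             HR = exp(unname(est)),
             ci_low = exp(unname(est - 1.96 * se)),
             ci_high = exp(unname(est + 1.96 * se)),
             p = unname(2 * pnorm(-abs(z))),
             stringsAsFactors = FALSE)
}

#' Joint Wald test for a set of coefficients
#'
#' Computes theta' V^{-1} theta for the named subset of packed
#' parameters, with degrees of freedom equal to the number of terms.
#'
#' @param fit a fitted model with \code{estimates} and \code{vcov}.
#' @param terms character vector of parameter names.
#' @return list with \code{chisq}, \code{df}, \code{p}.
#' @export
wald_test <- function(fit, terms) {
  if (is.null(fit$vcov)) stop("fit carries no covariance matrix",
                              call. = FALSE)
  if (!all(terms %in% names(fit$estimates)))
    stop("unknown term(s): ",
         paste(setdiff(terms, names(fit$estimates)), collapse = ", "),
         call. = FALSE)
  th <- fit$estimates[terms]
  V <- fit$vcov[terms, terms, drop = FALSE]
  Vi <- tryCatch(solve(V), error = function(e)
    stop("singular covariance for terms ", paste(terms, collapse = ", "),
         call. = FALSE))
  stat <- drop(t(th) %*% Vi %*% th)
  list(chisq = stat, df = length(terms),
       p = pchisq(stat, df = length(terms), lower.tail = FALSE))
}
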