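# Independent oracles and small fixture builders used across tests.

# Truncated-power natural cubic spline basis (textbook construction):
# N1 = 1, N2 = x, N_{k+2} = d_k - d_{K-1},
# d_k(x) = [(x - xi_k)_+^3 - (x - xi_K)_+^3] / (xi_K - xi_k),
# over all knots xi_1 < ... < xi_K (boundary + interior).
truncated_power_natural_basis <- function(x, knots) {
  K <- length(knots)
  dk <- function(k) {
    (pmax(x - knots[k], 0)^3 - pmax(x - knots[K], 0)^3) /
      (knots[K] - knots[k])
  }
  cols <- list(rep(1, length(x)), x)
  for (k in seq_len(K - 2L)) cols[[k + 2L]] <- dk(k) - dk(K - 1L)
  do.call(cbind, cols)
}

# Dense-grid integration oracle for the bivariate joint-model subject
# likelihood: integrates the full integrand over a wide b-grid
# (trapezoid via Riemann sum on a fine regular grid), evaluating the
# hazard from its definition at Gauss-Legendre nodes.
grid_loglik_oracle <- function(subject, visits, params, ngrid = 301,
                               width = 7) {
  Sb <- params$Sigma_b; Se <- params$Sigma_eps
  sds <- sqrt(diag(Sb))
  g1 <- seq(-width * sds[1], width * sds[1], length.out = ngrid)
  g2 <- seq(-width * sds[2], width * sds[2], length.out = ngrid)
  bb <- as.matrix(expand.grid(b1 = g1, b2 = g2))
  Y <- cbind(sqrt(visits$nd_area), sqrt(visits$d_area))
  des_nd <- build_marker_design(visits, subject, params$specs$nd,
                                params$marker_basis)
  des_d <- build_marker_design(visits, subject, params$specs$d,
                               params$marker_basis)
  mu <- cbind(drop(des_nd$X %*% params$beta$nd),
              drop(des_d$X %*% params$beta$d))
  Sei <- solve(Se); ldSe <- as.numeric(determinant(Se)$modulus)
  Sbi <- solve(Sb); ldSb <- as.numeric(determinant(Sb)$modulus)
  lv <- numeric(nrow(bb))
  for (j in seq_len(nrow(visits))) {
    Rj <- cbind(Y[j, 1] - mu[j, 1] - bb[, 1],
                Y[j, 2] - mu[j, 2] - bb[, 2])
    lv <- lv - log(2 * pi) - 0.5 * ldSe - 0.5 * rowSums((Rj %*% Sei) * Rj)
  }
  gl <- pracma::gaussLegendre(40, subject$entry_age, subject$exit_age)
  loghaz <- function(u, b1, b2) {
    # full log-hazard linear predictor, assembled from its definition
    mu_nd <- marker_mean(u, subject, params$specs$nd, params$beta$nd,
                         0, params$marker_basis)
    mu_d <- marker_mean(u, subject, params$specs$d, params$beta$d,
                        0, params$marker_basis)
    s0 <- cbind(1, eval_basis(params$hazard_basis, u))
    W <- mdjm:::covariate_design(subject,
                                 mdjm:::survival_covariate_set(params))
    wg <- drop(W[, names(params$gamma), drop = FALSE] %*% params$gamma)
    base <- drop(s0 %*% params$omega) + wg +
      params$alpha[["nd"]] * mu_nd + params$alpha[["d"]] * mu_d
    outer(params$alpha[["nd"]] * b1 + params$alpha[["d"]] * b2, base, "+")
  }
  Lam <- drop(exp(loghaz(gl$x, bb[, 1], bb[, 2])) %*% gl$w)
  loglam_T <- loghaz(subject$exit_age, bb[, 1], bb[, 2])[, 1]
  lpr <- -log(2 * pi) - 0.5 * ldSb - 0.5 * rowSums((bb %*% Sbi) * bb)
  vals <- lv + subject$event * loglam_T - Lam + lpr
  mx <- max(vals)
  mx + log(sum(exp(vals - mx))) + log(diff(g1)[1]) + log(diff(g2)[1])
}

# Bivariate parameter set matching the generator's (nd, d) block
bivariate_params <- function(tp = default_true_params("joint2")) {
  joint_params(tp$beta[c("nd", "d")], tp$Sigma_b[1:2, 1:2],
               tp$Sigma_eps[1:2, 1:2], tp$omega, tp$gamma,
               tp$alpha[c("nd", "d")], default_marker_specs("joint2"),
               tp$marker_basis, tp$hazard_basis)
}

# Small deterministic cohort for structural tests
toy_cohort <- function(n = 120, seed = 77, ...) {
  generate_cohort(synthetic_config(n_subjects = n, seed = seed, ...))
}

# Hand-rolled counting-process rows from explicit vectors
cp_rows <- function(start, stop, event, x) {
  data.frame(age_start = start, age_stop = stop, event = event, x = x)
}
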