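# Internal numerical helpers.

# log(sum(exp(x))) along rows of a matrix, guarded against overflow
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

logsumexp <- function(x) {
  mx <- max(x)
  mx + log(sum(exp(x - mx)))
}

# Cached Gauss-Hermite rules (physicists' weight exp(-x^2))
gh_rule <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (is.null(cache[[key]])) cache[[key]] <<- pracma::gaussHermite(n)
    cache[[key]]
  }
})

# Gauss-Legendre rule on [0, 1]; rescale per interval as needed
gl_rule01 <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (is.null(cache[[key]])) {
      cache[[key]] <<- if (n == 1L) list(x = 0.5, w = 1)
                       else pracma::gaussLegendre(n, 0, 1)
    }
    cache[[key]]
  }
})

# Log-Cholesky parameterization of a symmetric positive-definite matrix.
# theta holds the lower triangle column-wise with log-transformed diagonal.
chol_to_theta <- function(S) {
  L <- t(chol(S))
  th <- L[lower.tri(L, diag = TRUE)]
  idx <- which(lower.tri(L, diag = TRUE), arr.ind = TRUE)
  th[idx[, 1] == idx[, 2]] <- log(th[idx[, 1] == idx[, 2]])
  th
}

theta_to_chol <- function(th, d) {
  L <- matrix(0, d, d)
  idx <- which(lower.tri(L, diag = TRUE), arr.ind = TRUE)
  vals <- th
  on_diag <- idx[, 1] == idx[, 2]
  vals[on_diag] <- exp(vals[on_diag])
  L[idx] <- vals
  L
}

theta_to_cov <- function(th, d) {
  L <- theta_to_chol(th, d)
  L %*% t(L)
}

n_chol_par <- function(d) d * (d + 1L) / 2L

# covariance matrix -> correlation of off-diagonal (i, j)
cov2corr_ij <- function(S, i, j) S[i, j] / sqrt(S[i, i] * S[j, j])

is_pd <- function(S, tol = 1e-10) {
  if (!isTRUE(all.equal(S, t(S), tolerance = 1e-8))) return(FALSE)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  all(ev > tol * max(abs(ev), 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
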