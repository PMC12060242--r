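## Single-random-component linear mixed model fitted by REML on the spectral
## decomposition of the covariance kernel:
##
##   y = B b + g + e,   g ~ N(0, s2u * K),   e ~ N(0, s2e * I)
##
## B holds the fixed effects (intercept and any non-marker covariates such as
## the environment indicator). The restricted likelihood is profiled on the
## variance ratio delta = s2e / s2u in the basis orthogonal to B, then the
## BLUE/BLUP are recovered from the full-rank eigendecomposition of K.
## This is the classical closed-form route to rrBLUP (K = XX') and Gaussian
## kernel regression (K = RBF kernel); the MCMC route to the same estimands
## lives in the Gibbs samplers.

kernel_reml <- function(y, K, B, delta_fixed = NULL, tol = 1e-10) {
  n <- length(y)
  q <- ncol(B)
  qrB <- qr(B)
  Tmat <- qr.Q(qrB, complete = TRUE)[, (q + 1L):n, drop = FALSE]  # basis of B-perp
  M <- crossprod(Tmat, K %*% Tmat)
  eM <- eigen((M + t(M)) / 2, symmetric = TRUE)
  d <- pmax(eM$values, 0)
  eta <- as.vector(crossprod(eM$vectors, crossprod(Tmat, y)))
  m <- n - q

  reml_nll <- function(log_delta) {
    delta <- exp(log_delta)
    0.5 * (m * log(sum(eta^2 / (d + delta))) + sum(log(d + delta)))
  }
  if (is.null(delta_fixed)) {
    opt <- optimize(reml_nll, c(-14, 14), tol = 1e-8)
    delta <- exp(opt$minimum)
  } else delta <- delta_fixed
  s2u <- sum(eta^2 / (d + delta)) / m
  s2e <- delta * s2u

  eK <- eigen((K + t(K)) / 2, symmetric = TRUE)
  dv <- pmax(eK$values, 0) + delta          # V / s2u eigenvalues
  Vinv <- eK$vectors %*% (t(eK$vectors) / dv)  # (K + delta I)^-1 = V^-1 * s2u
  BtVB <- crossprod(B, Vinv %*% B)
  bhat <- solve(BtVB, crossprod(B, Vinv %*% y))
  alpha <- as.vector(Vinv %*% (y - B %*% bhat))  # so that ghat = K alpha
  list(b = setNames(as.vector(bhat), colnames(B)), alpha = alpha, delta = delta,
       s2u = s2u, s2e = s2e, ghat = as.vector(K %*% alpha))
}

## split a design into fixed-effect covariates (names starting with ".") and
## marker columns
split_design <- function(X) {
  if (is.null(colnames(X))) colnames(X) <- sprintf("x%d", seq_len(ncol(X)))
  fixed <- grepl("^\\.", colnames(X))
  list(B = cbind(`(Intercept)` = rep(1, nrow(X)),
                 X[, fixed, drop = FALSE]),
       Z = X[, !fixed, drop = FALSE],
       fixed = fixed)
}

## Gaussian kernel on mean squared dosage distance, exp(-h * d2)
rbf_kernel <- function(A, B, h) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  exp(-h * pmax(d2, 0) / ncol(A))
}

median_bandwidth <- function(Z) {
  d2 <- as.vector(dist(Z))^2 / ncol(Z)
  med <- median(d2[d2 > 0])
  if (!is.finite(med) || med <= 0) 1 else 1 / med
}
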