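#' Fit rrBLUP (ridge-regression BLUP)
#'
#' Marker effects are modelled as i.i.d. normal with a common variance,
#' `beta_j ~ N(0, s2b)`; the shrinkage level `lambda = s2e / s2b` is estimated
#' from the data. Two routes to the same estimand are provided:
#' `method = "reml"` (default) solves the mixed model in closed form on the
#' eigendecomposition of XX', and `method = "gibbs"` runs a Bayesian
#' ridge-regression Gibbs sampler (the paper-style configuration uses 12,000
#' iterations with 2,000 burn-in). Covariate columns named with a leading
#' `"."` are fitted as unshrunk fixed effects alongside the intercept.
#'
#' @param X complete design matrix (markers, plus optional "." covariates).
#' @param y numeric response.
#' @param hyper list; recognised entries `method` ("reml"/"gibbs"),
#'   `lambda` (fixed shrinkage, skips REML), `n_iter`, `burn_in`, `df0`, `R2`.
#' @param seed RNG seed (used by the Gibbs route).
#' @return a `gp_model` of kind `"rrblup"` whose state holds the intercept /
#'   fixed effects `b` and per-marker effects `beta`.
#' @export
fit_rrblup <- function(X, y, hyper = list(), seed = 1L) {
  X <- check_xy(X, y)
  h <- modifyList(list(method = "reml", lambda = NULL,
                       n_iter = 12000L, burn_in = 2000L, df0 = 5, R2 = 0.5),
                  hyper)
  if (sd(y) == 0) return(constant_y_model("rrblup", X, y, h, seed))
  sdg <- split_design(X)
  Z <- sdg$Z
  if (h$method == "reml") {
    fit <- kernel_reml(y, tcrossprod(Z), sdg$B, delta_fixed = h$lambda)
    beta <- as.vector(crossprod(Z, fit$alpha))
    state <- list(b = fit$b, beta = setNames(beta, colnames(Z)),
                  s2u = fit$s2u, s2e = fit$s2e, lambda = fit$delta)
  } else if (h$method == "gibbs") {
    if (h$n_iter <= h$burn_in) stopf("n_iter must exceed burn_in")
    sm <- with_seed(seed,
      gibbs_ridge(sdg$B, Z, y, h$n_iter, h$burn_in, h$df0, h$R2))
    state <- list(b = setNames(as.vector(sm$b), colnames(sdg$B)), beta = setNames(as.vector(sm$beta), colnames(Z)),
                  s2e = sm$s2e, s2b = sm$s2b)
  } else stopf("unknown rrblup method '%s'", h$method)
  new_gp_model("rrblup", state, h, seed, colnames(X))
}

#' @export
predict.gp_rrblup <- function(object, X_new, ...) {
  X_new <- check_newdata(object, X_new)
  sdg <- split_design(X_new)
  as.vector(sdg$B %*% object$state$b + sdg$Z %*% object$state$beta)
}

#' Fit BayesB (spike-and-slab marker effects)
#'
#' Gibbs sampler with a per-marker point-normal prior: each marker effect is
#' exactly zero with probability `pi` and otherwise drawn from a normal slab
#' whose variance has a scaled-inverse-chi-squared prior (a scaled-t slab
#' marginally). `pi` is itself updated under a Beta prior. Reported effects
#' are posterior means over the post-burn-in chain; `inclusion` holds the
#' posterior inclusion probability per marker.
#'
#' @inheritParams fit_rrblup
#' @param hyper list; `n_iter` (default 12000), `burn_in` (2000), `pi0`
#'   (prior mass at zero, default 0.5), `pi_counts` (Beta prior weight, 10),
#'   `df0` (slab degrees of freedom, 5), `R2` (prior fraction of variance
#'   attributed to markers, 0.5).
#' @return a `gp_model` of kind `"bayesb"`.
#' @export
fit_bayesb <- function(X, y, hyper = list(), seed = 1L) {
  X <- check_xy(X, y)
  h <- modifyList(list(n_iter = 12000L, burn_in = 2000L, pi0 = 0.5,
                       pi_counts = 10, df0 = 5, R2 = 0.5), hyper)
  if (h$n_iter <= h$burn_in) stopf("n_iter must exceed burn_in")
  if (sd(y) == 0) return(constant_y_model("bayesb", X, y, h, seed))
  sdg <- split_design(X)
  sm <- with_seed(seed,
    gibbs_bayesb(sdg$B, sdg$Z, y, h$n_iter, h$burn_in,
                 h$pi0, h$pi_counts, h$df0, h$R2))
  state <- list(b = setNames(as.vector(sm$b), colnames(sdg$B)), beta = setNames(as.vector(sm$beta), colnames(sdg$Z)),
                inclusion = setNames(as.vector(sm$inclusion), colnames(sdg$Z)),
                s2e = sm$s2e, pi = sm$pi)
  new_gp_model("bayesb", state, h, seed, colnames(X))
}

#' @export
predict.gp_bayesb <- predict.gp_rrblup

#' Fit RKHS regression (Gaussian kernel)
#'
#' Kernel regression on `K(u, v) = exp(-h * d2(u, v))` where `d2` is the mean
#' squared dosage difference across features. The default bandwidth is the
#' median heuristic `h = 1 / median(d2)`. The kernel coefficients are fitted
#' either by the closed-form REML mixed-model solve (default) or by a Gibbs
#' sampler on the kernel eigenbasis (`method = "gibbs"`).
#'
#' @inheritParams fit_rrblup
#' @param hyper list; `bandwidth` (positive; default median heuristic),
#'   `method`, `lambda`, `n_iter`, `burn_in`.
#' @return a `gp_model` of kind `"rkhs"`; its state keeps the training rows
#'   so test predictions can form the cross-kernel.
#' @export
fit_rkhs <- function(X, y, hyper = list(), seed = 1L) {
  X <- check_xy(X, y)
  h <- modifyList(list(method = "reml", bandwidth = NULL, lambda = NULL,
                       n_iter = 12000L, burn_in = 2000L, df0 = 5, R2 = 0.5),
                  hyper)
  if (!is.null(h$bandwidth) && h$bandwidth <= 0)
    stopf("kernel bandwidth must be positive")
  if (sd(y) == 0) return(constant_y_model("rkhs", X, y, h, seed))
  sdg <- split_design(X)
  Z <- sdg$Z
  bw <- h$bandwidth %||% median_bandwidth(Z)
  K <- rbf_kernel(Z, Z, bw)
  if (h$method == "reml") {
    fit <- kernel_reml(y, K, sdg$B, delta_fixed = h$lambda)
    state <- list(b = fit$b, alpha = fit$alpha, bandwidth = bw, Z_train = Z,
                  s2u = fit$s2u, s2e = fit$s2e)
  } else if (h$method == "gibbs") {
    if (h$n_iter <= h$burn_in) stopf("n_iter must exceed burn_in")
    eK <- eigen((K + t(K)) / 2, symmetric = TRUE)
    keep <- eK$values > max(eK$values) * 1e-10
    U <- eK$vectors[, keep, drop = FALSE]
    dv <- eK$values[keep]
    W <- U %*% diag(sqrt(dv), nrow = length(dv))   # g = W gamma, gamma iid
    sm <- with_seed(seed,
      gibbs_ridge(sdg$B, W, y, h$n_iter, h$burn_in, h$df0, h$R2))
    alpha <- as.vector(U %*% (as.vector(sm$beta) / sqrt(dv)))
    state <- list(b = setNames(as.vector(sm$b), colnames(sdg$B)), alpha = alpha, bandwidth = bw, Z_train = Z,
                  s2e = sm$s2e)
  } else stopf("unknown rkhs method '%s'", h$method)
  new_gp_model("rkhs", state, h, seed, colnames(X))
}

#' @export
predict.gp_rkhs <- function(object, X_new, ...) {
  X_new <- check_newdata(object, X_new)
  if (isTRUE(object$state$constant)) {
    sdg <- split_design(X_new)
    return(as.vector(sdg$B %*% object$state$b))
  }
  sdg <- split_design(X_new)
  Kc <- rbf_kernel(sdg$Z, object$state$Z_train, object$state$bandwidth)
  as.vector(sdg$B %*% object$state$b + Kc %*% object$state$alpha)
}
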