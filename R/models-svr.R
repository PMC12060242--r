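#' Fit epsilon-insensitive support vector regression (RBF kernel)
#'
#' Solves the epsilon-SVR dual by sequential minimal optimisation with
#' maximal-violating-pair working-set selection: residuals inside the
#' epsilon tube incur no loss, slack beyond it is penalised at weight `C`.
#' Defaults mirror the common library defaults: `C = 1`, `epsilon = 0.1`,
#' RBF width `gamma = 1 / (p * Var(X))`.
#'
#' @inheritParams fit_rrblup
#' @param hyper list; `C` (penalty weight > 0), `epsilon` (tube half-width),
#'   `gamma` (RBF width), `tol` (KKT violation tolerance), `max_iter`.
#' @param seed unused (the solver is deterministic); kept for the contract.
#' @return a `gp_model` of kind `"svr"` storing the support coefficients
#'   `beta = alpha - alpha*`, the intercept `b` and the support vectors.
#' @export
fit_svr <- function(X, y, hyper = list(), seed = 1L) {
  X <- check_xy(X, y)
  h <- modifyList(list(C = 1, epsilon = 0.1, gamma = NULL,
                       tol = 1e-6, max_iter = 200000L), hyper)
  if (h$C <= 0) stopf("penalty weight C must be positive")
  if (h$epsilon < 0) stopf("epsilon must be non-negative")
  h$gamma <- h$gamma %||% {
    v <- var(as.vector(X)) * (length(X) - 1) / length(X)
    1 / (ncol(X) * max(v, 1e-12))
  }
  K <- svr_kernel(X, X, h$gamma)
  sol <- smo_svr(K, y, h$C, h$epsilon, h$tol, h$max_iter)
  sv <- which(abs(sol$beta) > 1e-12)
  if (!length(sv)) sv <- integer()
  new_gp_model("svr",
               list(beta = sol$beta[sv], b = sol$b, sv = sv,
                    X_sv = X[sv, , drop = FALSE], gamma = h$gamma,
                    converged = sol$converged, iterations = sol$iterations),
               h, seed, colnames(X))
}

svr_kernel <- function(A, B, gamma) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

## SMO on the 2n-variable dual: z = (alpha+, alpha-), signs s = (+1, -1),
## minimise 0.5 b'Kb - y'b + eps * sum(z) with b = alpha+ - alpha-,
## subject to sum(s * z) = 0 and 0 <= z <= C.
smo_svr <- function(K, y, C, eps, tol, max_iter) {
  n <- length(y)
  z <- numeric(2L * n)
  beta <- numeric(n)
  Kb <- numeric(n)
  s <- rep(c(1, -1), each = n)
  orig <- rep(seq_len(n), 2L)
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    G <- c(Kb + eps - y, -Kb + eps + y)
    viol <- -s * G
    # libsvm-style maximal violating pair for one equality constraint:
    # I_up can push the constraint sum up, I_low can pull it down
    in_up <- (s > 0 & z < C - 1e-12) | (s < 0 & z > 1e-12)
    in_low <- (s > 0 & z > 1e-12) | (s < 0 & z < C - 1e-12)
    if (!any(in_up) || !any(in_low)) { converged <- TRUE; break }
    i <- which(in_up)[which.max(viol[in_up])]
    j <- which(in_low)[which.min(viol[in_low])]
    if (viol[i] - viol[j] < tol) { converged <- TRUE; break }
    oi <- orig[i]; oj <- orig[j]
    # step moves beta[oi] by +lam and beta[oj] by -lam regardless of signs
    a <- K[oi, oi] + K[oj, oj] - 2 * K[oi, oj]
    if (a <= 1e-12) a <- 1e-12
    lam <- (viol[i] - viol[j]) / a
    lam <- min(lam,
               if (s[i] > 0) C - z[i] else z[i],
               if (s[j] > 0) z[j] else C - z[j])
    if (lam <= 0) break
    z[i] <- z[i] + s[i] * lam
    z[j] <- z[j] - s[j] * lam
    beta[oi] <- beta[oi] + lam
    beta[oj] <- beta[oj] - lam
    Kb <- Kb + lam * (K[, oi] - K[, oj])
  }
  ap <- z[seq_len(n)]; am <- z[n + seq_len(n)]
  free_p <- ap > 1e-9 & ap < C - 1e-9
  free_m <- am > 1e-9 & am < C - 1e-9
  if (any(free_p) || any(free_m)) {
    b <- mean(c((y - Kb - eps)[free_p], (y - Kb + eps)[free_m]))
  } else {
    lower <- suppressWarnings(max((y - Kb - eps)[ap <= 1e-9],
                                  (y - Kb + eps)[am >= C - 1e-9]))
    upper <- suppressWarnings(min((y - Kb - eps)[ap >= C - 1e-9],
                                  (y - Kb + eps)[am <= 1e-9]))
    if (!is.finite(lower)) lower <- upper
    if (!is.finite(upper)) upper <- lower
    b <- (lower + upper) / 2
  }
  list(beta = beta, b = b, converged = converged || it < max_iter,
       iterations = it)
}

#' @export
predict.gp_svr <- function(object, X_new, ...) {
  X_new <- check_newdata(object, X_new)
  st <- object$state
  if (!length(st$sv)) return(rep(st$b, nrow(X_new)))
  Kc <- svr_kernel(X_new, st$X_sv, st$gamma)
  as.vector(Kc %*% st$beta + st$b)
}
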