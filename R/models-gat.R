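#' Fit a star-graph attention network
#'
#' Each record is viewed as a heterogeneous star graph: one node per marker
#' with directed edges into a single phenotype node and no marker-marker
#' edges. A marker node's feature vector is its dosage together with its
#' identity (a one-hot indicator: different markers carry different
#' information, so the node feature must say which marker it is — with
#' anonymous scalar features an attention layer over a star is
#' neighbour-permutation-invariant and cannot credit signal to specific
#' SNPs). Three attention layers update the phenotype node: attention logits
#' are a LeakyReLU of combined source and target projections, normalised by a
#' softmax over the in-neighbourhood (single head); the attended message sum
#' passes through an ELU on the hidden layers and identity at the regression
#' output. Under one-hot identity features the source projection of marker j
#' collapses to `w * x_j + U[, j]` and its attention logit to
#' `c * x_j + e_j + (target term)`, which is the parameterisation trained
#' here, by minibatch AdamW on the standardized response.
#'
#' @inheritParams fit_rrblup
#' @param hyper list; `hidden` (channels, default 20), `epochs` (50),
#'   `batch_size` (8), `lr` (0.005), `weight_decay` (0), `slope` (LeakyReLU
#'   negative slope, 0.01).
#' @return a `gp_model` of kind `"gat"`.
#' @export
fit_gat <- function(X, y, hyper = list(), seed = 1L) {
  X <- check_xy(X, y)
  h <- modifyList(list(hidden = 20L, epochs = 50L, batch_size = 8L,
                       lr = 0.005, weight_decay = 0, slope = 0.01), hyper)
  if (h$epochs <= 0) stopf("epochs must be positive")
  if (sd(y) == 0) return(constant_y_model("gat", X, y, h, seed))
  y_mean <- mean(y); y_sd <- sd(y)
  ys <- (y - y_mean) / y_sd
  n <- nrow(X); p <- ncol(X)

  with_seed(seed, {
    theta <- gat_init(h$hidden, p)
    opt <- list(m = numeric(length(theta)), v = numeric(length(theta)), t = 0L)
    for (ep in seq_len(h$epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = h$batch_size)) {
        rows <- ord[start:min(start + h$batch_size - 1L, n)]
        fw <- gat_forward(theta, X[rows, , drop = FALSE], h)
        dpred <- 2 * (fw$pred - ys[rows]) / length(rows)
        gr <- gat_backward(theta, fw, dpred, h)$dtheta
        opt$t <- opt$t + 1L
        opt$m <- 0.9 * opt$m + 0.1 * gr
        opt$v <- 0.999 * opt$v + 0.001 * gr^2
        mh <- opt$m / (1 - 0.9^opt$t)
        vh <- opt$v / (1 - 0.999^opt$t)
        theta <- theta - h$lr * (mh / (sqrt(vh) + 1e-8) + h$weight_decay * theta)
      }
    }
    new_gp_model("gat", list(theta = theta, p = p, y_mean = y_mean, y_sd = y_sd),
                 h, seed, colnames(X))
  })
}

## per layer l: message weights w_l (H), U_l (H x p, identity part), bias
## b_l (H), attention source scalar c_l, attention identity e_l (p), and for
## l >= 2 the target attention vector q_l (H_{l-1}); output layer has H = 1.
gat_index <- function(H, p) {
  sizes <- c(w1 = H, U1 = H * p, b1 = H, c1 = 1L, e1 = p,
             w2 = H, U2 = H * p, b2 = H, c2 = 1L, e2 = p, q2 = H,
             w3 = 1L, U3 = p, b3 = 1L, c3 = 1L, e3 = p, q3 = H)
  ends <- cumsum(sizes)
  mapply(function(e, s) (e - s + 1L):e, ends, sizes, SIMPLIFY = FALSE)
}

gat_init <- function(H, p) {
  ix <- gat_index(H, p)
  theta <- numeric(max(unlist(ix)))
  glorot <- function(m, fi, fo) runif(m, -1, 1) * sqrt(6 / (fi + fo))
  theta[ix$w1] <- glorot(H, p + 1, H); theta[ix$U1] <- glorot(H * p, p + 1, H)
  theta[ix$w2] <- glorot(H, p + 1, H); theta[ix$U2] <- glorot(H * p, p + 1, H)
  theta[ix$w3] <- glorot(1, p + 1, 1); theta[ix$U3] <- glorot(p, p + 1, 1)
  theta[ix$c1] <- glorot(1, 2, 1); theta[ix$c2] <- glorot(1, 2, 1)
  theta[ix$c3] <- glorot(1, 2, 1)
  theta[ix$q2] <- glorot(H, H, 1); theta[ix$q3] <- glorot(H, H, 1)
  # attention identity offsets start at zero (uniform attention over markers)
  theta
}

lrelu <- function(x, slope) ifelse(x > 0, x, slope * x)
lrelu_grad <- function(x, slope) ifelse(x > 0, 1, slope)
elu <- function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1)
elu_grad <- function(x) ifelse(x > 0, 1, exp(pmin(x, 0)))

row_softmax <- function(E) {
  E <- exp(E - apply(E, 1, max))
  E / rowSums(E)
}

## attention layer on a batch: logits lrelu(c x_j + e_j + d_i), softmax over
## markers j; returns the attention matrix P and the attended dosage sum s
gat_layer <- function(X, cc, e, d, slope) {
  arg <- cc * X + rep(e, each = nrow(X)) + d
  P <- row_softmax(lrelu(arg, slope))
  list(arg = arg, P = P, s = rowSums(P * X))
}

gat_forward <- function(theta, X, h) {
  H <- h$hidden; p <- ncol(X); ix <- gat_index(H, p)
  U1 <- matrix(theta[ix$U1], H, p); U2 <- matrix(theta[ix$U2], H, p)
  nb <- nrow(X)
  l1 <- gat_layer(X, theta[ix$c1], theta[ix$e1], 0, h$slope)
  A1 <- outer(l1$s, theta[ix$w1]) + l1$P %*% t(U1) +
    rep(theta[ix$b1], each = nb)
  Z1 <- elu(A1)
  d2 <- as.vector(Z1 %*% theta[ix$q2])
  l2 <- gat_layer(X, theta[ix$c2], theta[ix$e2], d2, h$slope)
  A2 <- outer(l2$s, theta[ix$w2]) + l2$P %*% t(U2) +
    rep(theta[ix$b2], each = nb)
  Z2 <- elu(A2)
  d3 <- as.vector(Z2 %*% theta[ix$q3])
  l3 <- gat_layer(X, theta[ix$c3], theta[ix$e3], d3, h$slope)
  pred <- theta[ix$w3] * l3$s + as.vector(l3$P %*% theta[ix$U3]) + theta[ix$b3]
  list(X = X, l1 = l1, A1 = A1, Z1 = Z1, l2 = l2, A2 = A2, Z2 = Z2,
       l3 = l3, pred = pred)
}

gat_backward <- function(theta, fw, dpred, h) {
  X <- fw$X
  H <- h$hidden; p <- ncol(X); ix <- gat_index(H, p)
  U1 <- matrix(theta[ix$U1], H, p); U2 <- matrix(theta[ix$U2], H, p)
  dtheta <- numeric(length(theta))
  dX <- matrix(0, nrow(X), p)

  # backward through one attention layer given dP (grad wrt attention
  # weights) and ds (grad wrt attended dosage sum); returns input-side grads
  layer_back <- function(l, cc, dP, ds) {
    dP <- dP + ds * X                       # s = sum_j P_j x_j
    dE <- l$P * (dP - rowSums(dP * l$P))    # softmax backward
    dArg <- dE * lrelu_grad(l$arg, h$slope)
    list(dc = sum(dArg * X), de = colSums(dArg), dd = rowSums(dArg),
         dX = dArg * cc + ds * l$P)
  }

  ## output layer
  dtheta[ix$w3] <- sum(dpred * fw$l3$s)
  dtheta[ix$b3] <- sum(dpred)
  dtheta[ix$U3] <- as.vector(crossprod(fw$l3$P, dpred))
  ds3 <- dpred * theta[ix$w3]
  dP3 <- outer(dpred, theta[ix$U3])
  b3 <- layer_back(fw$l3, theta[ix$c3], dP3, ds3)
  dtheta[ix$c3] <- b3$dc; dtheta[ix$e3] <- b3$de
  dX <- dX + b3$dX
  dtheta[ix$q3] <- as.vector(crossprod(fw$Z2, b3$dd))
  dZ2 <- outer(b3$dd, theta[ix$q3])

  ## layer 2
  dA2 <- dZ2 * elu_grad(fw$A2)
  dtheta[ix$w2] <- as.vector(crossprod(dA2, fw$l2$s))
  dtheta[ix$b2] <- colSums(dA2)
  dtheta[ix$U2] <- as.vector(crossprod(dA2, fw$l2$P))
  ds2 <- as.vector(dA2 %*% theta[ix$w2])
  dP2 <- dA2 %*% U2
  b2 <- layer_back(fw$l2, theta[ix$c2], dP2, ds2)
  dtheta[ix$c2] <- b2$dc; dtheta[ix$e2] <- b2$de
  dX <- dX + b2$dX
  dtheta[ix$q2] <- as.vector(crossprod(fw$Z1, b2$dd))
  dZ1 <- outer(b2$dd, theta[ix$q2])

  ## layer 1
  dA1 <- dZ1 * elu_grad(fw$A1)
  dtheta[ix$w1] <- as.vector(crossprod(dA1, fw$l1$s))
  dtheta[ix$b1] <- colSums(dA1)
  dtheta[ix$U1] <- as.vector(crossprod(dA1, fw$l1$P))
  ds1 <- as.vector(dA1 %*% theta[ix$w1])
  dP1 <- dA1 %*% U1
  b1 <- layer_back(fw$l1, theta[ix$c1], dP1, ds1)
  dtheta[ix$c1] <- b1$dc; dtheta[ix$e1] <- b1$de
  dX <- dX + b1$dX

  list(dtheta = dtheta, dX = dX)
}

#' @export
predict.gp_gat <- function(object, X_new, ...) {
  X_new <- check_newdata(object, X_new)
  st <- object$state
  if (isTRUE(st$constant)) {
    sdg <- split_design(X_new)
    return(as.vector(sdg$B %*% st$b))
  }
  fw <- gat_forward(st$theta, X_new, object$hyper)
  fw$pred * st$y_sd + st$y_mean
}

#' @export
model_gradient.gp_gat <- function(object, X) {
  X <- check_newdata(object, X)
  st <- object$state
  fw <- gat_forward(st$theta, X, object$hyper)
  bk <- gat_backward(st$theta, fw, rep(1, nrow(X)), object$hyper)
  bk$dX * st$y_sd
}
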