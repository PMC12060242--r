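# Marker-effect attribution: coefficients, Shapley, impurity, integrated
# gradients, pairwise association report.

test_that("coefficient effects come from beta, excluding covariates", {
  withr::with_seed(31, {
    X <- cbind(matrix(rbinom(300 * 6, 2, 0.4), 300), .env = rep(0:1, 150))
    colnames(X)[1:6] <- sprintf("m%d", 1:6)
    y <- 2 * X[, 1] + rnorm(300, 0, 0.5)
  })
  fit <- fit_rrblup(X, y)
  tab <- effects_from_coefficients(fit)
  expect_equal(nrow(tab), 6)
  expect_false(".env" %in% tab$marker_id)
  # near-orthogonal markers: effect close to the generative coefficient
  expect_lt(abs(tab$effect[1] - 2), 0.4)
  expect_error(effects_from_coefficients(fit_rf(X, y,
                                                hyper = list(n_trees = 5))),
               "rrblup/bayesb")
  # null trait: all effects shrink to zero
  withr::with_seed(32, y0 <- rnorm(300))
  expect_lt(max(abs(effects_from_coefficients(fit_rrblup(X, y0))$effect)),
            0.15)
})

test_that("Shapley sampler is exact for linear models and ignores dummies", {
  withr::with_seed(33, {
    bg <- matrix(rnorm(40 * 4), 40, 4, dimnames = list(NULL, paste0("m", 1:4)))
    Xt <- matrix(rnorm(2 * 4), 2, 4, dimnames = list(NULL, paste0("m", 1:4)))
  })
  beta <- c(2, -1, 0.5, 0)
  f <- function(M) as.vector(M %*% beta)
  sh <- shapley_effects(f, Xt, bg, n_samples = 400, seed = 5)
  per <- attr(sh, "per_ril")
  closed <- sweep(Xt, 2, colMeans(bg)) %*% diag(beta)
  # MC tolerance: the background draw is the only randomness for linear f
  expect_lt(max(abs(per - closed)), 0.2)
  # dummy feature (beta = 0) gets ~zero attribution
  expect_lt(max(abs(per[, 4])), 1e-10)
  expect_error(shapley_effects(f, Xt[0, , drop = FALSE], bg), "empty test")
  expect_error(shapley_effects(f, Xt, bg[0, , drop = FALSE]), "background")
})

test_that("Shapley sampler matches exhaustive enumeration within 3 SE", {
  withr::with_seed(34, {
    bg <- matrix(rnorm(15 * 4), 15, 4, dimnames = list(NULL, paste0("m", 1:4)))
    x <- rnorm(4)
  })
  f <- function(M) M[, 1] * M[, 2] + 2 * M[, 3] - 0.5 * M[, 4]^2
  exact <- exact_shapley(f, x, bg)
  n_samp <- 400
  sh <- shapley_effects(f, matrix(x, 1, dimnames = list(NULL, paste0("m", 1:4))),
                        bg, n_samples = n_samp, seed = 6)
  # conservative per-feature MC standard error from the prediction spread
  se <- 3 * sd(f(bg)) / sqrt(n_samp)
  expect_true(all(abs(attr(sh, "per_ril")[1, ] - exact) < 3 * pmax(se, 0.02)))
})

test_that("impurity importances are normalised and zero for unused features", {
  withr::with_seed(35, {
    X <- matrix(rbinom(200 * 5, 2, 0.4), 200)
    X[, 5] <- 1  # constant, can never be split on
    colnames(X) <- sprintf("m%d", 1:5)
    y <- 2 * X[, 2] + rnorm(200, 0, 0.3)
  })
  m <- fit_rf(X, y, hyper = list(n_trees = 30), seed = 7)
  tab <- impurity_importance(m)
  expect_equal(sum(tab$effect), 1)
  expect_true(all(tab$effect >= 0))
  expect_equal(tab$effect[5], 0)
  expect_error(impurity_importance(fit_rrblup(X, y)), "rf")
})

test_that("integrated gradients: baseline zero, linear exactness, any m", {
  beta <- c(1.5, -2, 0.25)
  lm3 <- linear_model(setNames(beta, paste0("m", 1:3)))
  X <- matrix(c(1, 2, 0, 0.5, 1, 2), 2, 3, byrow = TRUE,
              dimnames = list(NULL, paste0("m", 1:3)))
  for (m_steps in c(1, 4, 128)) {
    ig <- integrated_gradients(lm3, X, m_steps = m_steps)
    per <- attr(ig, "per_ril")
    expect_equal(per, sweep(X, 2, beta, "*"), ignore_attr = TRUE)
  }
  # x = baseline: all attributions vanish
  ig0 <- integrated_gradients(lm3, matrix(0, 1, 3,
                                          dimnames = list(NULL, paste0("m", 1:3))))
  expect_equal(as.numeric(attr(ig0, "per_ril")), c(0, 0, 0))
  expect_error(integrated_gradients(lm3, X, baseline = c(0, 0)), "baseline")
})

test_that("integrated gradients on a trained GAT satisfy completeness", {
  pop <- sim_population(120, 1, 10, seed = 91)
  des <- sim_trait_design(pop, qtl = 3, effects = 2, h2 = 0.9, seed = 92)
  m <- fit_gat(des$X, des$y, hyper = list(epochs = 15), seed = 8)
  Xt <- des$X[1:6, , drop = FALSE]
  ig <- integrated_gradients(m, Xt, m_steps = 128)
  per <- attr(ig, "per_ril")
  f1 <- predict(m, Xt)
  f0 <- predict(m, matrix(0, 1, ncol(Xt),
                          dimnames = list(NULL, colnames(Xt))))
  gap <- f1 - as.vector(f0)
  expect_true(all(abs(rowSums(per) - gap) <= 0.01 * pmax(abs(gap), 0.1)))
})

test_that("pairwise associations are symmetric with unit diagonal", {
  withr::with_seed(36, {
    P <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
    pm <- prediction_matrix(P, rnorm(20))
    E <- cbind(a = rnorm(10), b = rnorm(10))
    rownames(E) <- paste0("m", 1:10)
  })
  out <- pairwise_associations(pm, E, qtl_markers = c("m1", "m2"))
  expect_equal(diag(out$prediction_cor), rep(1, 3), ignore_attr = TRUE)
  expect_equal(out$prediction_cor, t(out$prediction_cor))
  expect_equal(out$effect_cor, t(out$effect_cor))
  expect_equal(sum(out$effects$qtl), 4)  # 2 markers x 2 models
  # constructed pattern: identical columns correlate exactly
  pm2 <- prediction_matrix(cbind(x = P[, 1], y = P[, 1], z = rev(P[, 1])),
                           rnorm(20))
  out2 <- pairwise_associations(pm2)
  expect_equal(out2$prediction_cor["x", "y"], 1)
})
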