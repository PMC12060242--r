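#' Marker effects from linear-model coefficients
#'
#' For rrBLUP and BayesB the estimated allele substitution effect is the
#' fitted per-marker coefficient; covariates (leading-"." columns such as the
#' environment indicator) are excluded.
#'
#' @param model a `gp_model` of kind rrblup or bayesb.
#' @return a `marker_effect_table`: data frame (model_kind, marker_id, effect).
#' @export
effects_from_coefficients <- function(model) {
  if (!inherits(model, "gp_model") || !model$kind %in% c("rrblup", "bayesb"))
    stopf("coefficient effects are defined for rrblup/bayesb models")
  beta <- model$state$beta
  marker_effect_table(model$kind, names(beta), as.numeric(beta))
}

marker_effect_table <- function(kind, marker_id, effect, n_test = NA_integer_) {
  structure(data.frame(model_kind = kind, marker_id = marker_id,
                       effect = effect, n_test_rils = n_test,
                       stringsAsFactors = FALSE),
            class = c("marker_effect_table", "data.frame"))
}

#' Monte-Carlo Shapley marker effects
#'
#' Permutation-sampling estimate of each feature's Shapley value for every
#' test record: for each sampled permutation a background row supplies the
#' "absent" feature values and the marginal change in prediction when a
#' feature joins is credited to it. Averaging over permutations (and
#' background draws) estimates the exact subset-weighted Shapley sum;
#' averaging over test records gives the reported per-marker effect.
#'
#' @param predict_fn function(matrix) -> numeric predictions.
#' @param X_test matrix of test rows to explain.
#' @param background matrix of background rows (typically the training set).
#' @param n_samples permutations per test row.
#' @param seed RNG seed.
#' @param model_kind label for the output table.
#' @return a `marker_effect_table` (averaged over test rows) with attribute
#'   `per_ril` holding the record-level matrix.
#' @export
shapley_effects <- function(predict_fn, X_test, background, n_samples = 64L,
                            seed = 1L, model_kind = "model") {
  X_test <- as.matrix(X_test); background <- as.matrix(background)
  if (nrow(X_test) == 0L) stopf("empty test set")
  if (nrow(background) == 0L) stopf("empty background set")
  if (n_samples < 1L) stopf("n_samples must be >= 1")
  p <- ncol(X_test)
  phi <- matrix(0, nrow(X_test), p, dimnames = list(NULL, colnames(X_test)))
  with_seed(seed, {
    for (r in seq_len(nrow(X_test))) {
      x <- X_test[r, ]
      for (s in seq_len(n_samples)) {
        perm <- sample.int(p)
        b <- background[sample.int(nrow(background), 1L), ]
        # walk the permutation: row k has the first k features set to x
        steps <- matrix(b, p + 1L, p, byrow = TRUE,
                        dimnames = list(NULL, colnames(X_test)))
        for (k in seq_len(p))
          steps[(k + 1L):(p + 1L), perm[k]] <- x[perm[k]]
        f <- predict_fn(steps)
        phi[r, perm] <- phi[r, perm] + diff(f)
      }
    }
    phi <- phi / n_samples
  })
  out <- marker_effect_table(model_kind, colnames(phi) %||% sprintf("x%d", 1:p),
                             colMeans(phi), n_test = nrow(X_test))
  attr(out, "per_ril") <- phi
  out
}

#' Impurity importance from a random forest
#'
#' Summed variance-reduction gains per feature over all splits and trees,
#' normalised to sum to one.
#'
#' @param model a `gp_model` of kind rf.
#' @return a `marker_effect_table` of non-negative importances.
#' @export
impurity_importance <- function(model) {
  if (!inherits(model, "gp_model") || model$kind != "rf")
    stopf("impurity importance is defined for rf models")
  imp <- model$state$importance
  tot <- sum(imp)
  marker_effect_table("rf", names(imp), if (tot > 0) imp / tot else imp)
}

#' Integrated-gradients marker effects
#'
#' Right-Riemann approximation of the path integral of model gradients from a
#' baseline to each test record,
#' `IG(x_i) = (x_i - x'_i) * sum_k dF(x' + k/m (x - x')) / dx_i / m`,
#' computed per (record, feature) and averaged over test records. Works for
#' any model with a `model_gradient()` method (the GAT, or [linear_model()]
#' for which `IG = beta * (x - x')` exactly).
#'
#' @param model a differentiable `gp_model`.
#' @param X_test matrix of test rows.
#' @param baseline baseline feature vector (default all zeros, the
#'   "no donor allele" reference).
#' @param m_steps interpolation steps.
#' @return a `marker_effect_table` with attribute `per_ril`.
#' @export
integrated_gradients <- function(model, X_test, baseline = NULL, m_steps = 128L) {
  X_test <- as.matrix(X_test)
  if (m_steps < 1L) stopf("m_steps must be >= 1")
  baseline <- baseline %||% rep(0, ncol(X_test))
  if (length(baseline) != ncol(X_test))
    stopf("baseline length does not match feature count")
  ig <- matrix(0, nrow(X_test), ncol(X_test),
               dimnames = list(NULL, colnames(X_test)))
  for (r in seq_len(nrow(X_test))) {
    diffs <- X_test[r, ] - baseline
    path <- outer(seq_len(m_steps) / m_steps, diffs) +
      matrix(baseline, m_steps, ncol(X_test), byrow = TRUE)
    colnames(path) <- colnames(X_test)
    G <- model_gradient(model, path)
    ig[r, ] <- diffs * colMeans(G)
  }
  out <- marker_effect_table(model$kind, colnames(X_test) %||%
                               sprintf("x%d", seq_len(ncol(X_test))),
                             colMeans(ig), n_test = nrow(X_test))
  attr(out, "per_ril") <- ig
  out
}

#' Pairwise association of models
#'
#' Pearson correlation matrices over model pairs for (a) predicted phenotypes
#' (from a [prediction_matrix()]) and (b) estimated marker effects (markers x
#' models), with optional ground-truth QTL labels attached per marker.
#'
#' @param pm a [prediction_matrix()] (or NULL).
#' @param effects matrix of marker effects, markers x models (or NULL).
#' @param qtl_markers character vector of ground-truth QTL marker ids.
#' @return list with `prediction_cor`, `effect_cor` and `effects` (long data
#'   frame with `qtl` flag) — entries NULL when the input was.
#' @export
pairwise_associations <- function(pm = NULL, effects = NULL,
                                  qtl_markers = character()) {
  pred_cor <- eff_cor <- eff_df <- NULL
  if (!is.null(pm)) {
    if (ncol(pm$predictions) < 2L) stopf("need at least 2 models")
    pred_cor <- cor(pm$predictions)
  }
  if (!is.null(effects)) {
    effects <- as.matrix(effects)
    if (ncol(effects) < 2L) stopf("need at least 2 models")
    eff_cor <- cor(effects)
    eff_df <- data.frame(
      marker_id = rep(rownames(effects) %||%
                        sprintf("m%d", seq_len(nrow(effects))), ncol(effects)),
      model_kind = rep(colnames(effects), each = nrow(effects)),
      effect = as.vector(effects))
    eff_df$qtl <- eff_df$marker_id %in% qtl_markers
  }
  list(prediction_cor = pred_cor, effect_cor = eff_cor, effects = eff_df)
}
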