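#' Fit a random forest regressor
#'
#' Bootstrap-aggregated regression trees grown to purity with
#' variance-reduction splits (the impurity gap `SSE(t) - SSE(tL) - SSE(tR)`
#' maximised at each node). Predictions average over trees. Per-feature
#' impurity importances (summed gains over all splits and trees) are stored
#' for [impurity_importance()].
#'
#' @inheritParams fit_rrblup
#' @param hyper list; `n_trees` (default 1000), `mtry` (features tried per
#'   split, default `max(1, floor(p / 3))`).
#' @return a `gp_model` of kind `"rf"`.
#' @export
fit_rf <- function(X, y, hyper = list(), seed = 1L) {
  X <- check_xy(X, y)
  h <- modifyList(list(n_trees = 1000L, mtry = NULL), hyper)
  h$mtry <- h$mtry %||% max(1L, floor(ncol(X) / 3))
  forest <- with_seed(seed, rf_build(X, y, as.integer(h$n_trees),
                                     as.integer(h$mtry)))
  imp <- setNames(as.vector(forest$importance), colnames(X))
  new_gp_model("rf", list(forest = forest, importance = imp),
               h, seed, colnames(X))
}

#' @export
predict.gp_rf <- function(object, X_new, ...) {
  X_new <- check_newdata(object, X_new)
  as.vector(rf_predict_cpp(object$state$forest, X_new))
}
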