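#' @title The fit/predict contract
#' @description All six predictors return a `gp_model`: a tagged list with the
#'   model kind, an opaque `state`, the hyperparameters actually used, the
#'   seed, and the training feature names. `predict()` is a pure function of
#'   (state, new design matrix); the new matrix must carry the training
#'   columns in the same order. Columns whose name starts with `"."` (the
#'   environment indicator `".env"`) are treated as ordinary covariates by
#'   the machine-learning models and as unshrunk fixed effects by the linear
#'   models.
#' @name gp_model
NULL

new_gp_model <- function(kind, state, hyper, seed, feature_names) {
  structure(list(kind = kind, state = state, hyper = hyper, seed = seed,
                 feature_names = feature_names),
            class = c(paste0("gp_", kind), "gp_model"))
}

#' @export
print.gp_model <- function(x, ...) {
  cat(sprintf("<gp_model:%s> p = %d features\n", x$kind, length(x$feature_names)))
  invisible(x)
}

check_xy <- function(X, y) {
  X <- as.matrix(X)
  if (anyNA(X)) stopf("design matrix must be complete (impute first)")
  if (nrow(X) != length(y)) stopf("X and y disagree on the number of records")
  if (nrow(X) < 2L) stopf("need at least 2 training records")
  if (is.null(colnames(X))) colnames(X) <- sprintf("x%d", seq_len(ncol(X)))
  X
}

check_newdata <- function(object, X_new) {
  X_new <- as.matrix(X_new)
  if (is.null(colnames(X_new))) colnames(X_new) <- object$feature_names
  if (ncol(X_new) != length(object$feature_names) ||
      !identical(colnames(X_new), object$feature_names))
    stopf("newdata columns do not match the %d training features",
          length(object$feature_names))
  X_new
}

constant_y_model <- function(kind, X, y, hyper, seed) {
  warning(sprintf("response is constant; %s returns a constant predictor", kind),
          call. = FALSE)
  sd <- split_design(X)
  new_gp_model(kind,
               state = list(constant = TRUE,
                            b = setNames(c(mean(y), rep(0, ncol(sd$B) - 1L)),
                                         colnames(sd$B)),
                            beta = setNames(rep(0, ncol(sd$Z)), colnames(sd$Z))),
               hyper, seed, colnames(X))
}

## gradient of the prediction surface with respect to inputs, where defined
model_gradient <- function(object, X) UseMethod("model_gradient")

#' Explicit linear predictor (internal utility model)
#'
#' A `gp_model` computing `intercept + X %*% beta`. Used as a stub model in
#' orchestration tests and as the closed-form reference for attribution
#' methods (its Shapley values and integrated gradients are known exactly).
#'
#' @param beta named coefficient vector (names = feature names).
#' @param intercept scalar intercept.
#' @return a `gp_model` of kind `"linear"`.
#' @export
linear_model <- function(beta, intercept = 0) {
  if (is.null(names(beta))) names(beta) <- sprintf("x%d", seq_along(beta))
  new_gp_model("linear", list(beta = beta, intercept = intercept),
               hyper = list(), seed = NA_integer_, feature_names = names(beta))
}

#' @export
predict.gp_linear <- function(object, X_new, ...) {
  X_new <- check_newdata(object, X_new)
  as.vector(object$state$intercept + X_new %*% object$state$beta)
}

#' @export
model_gradient.gp_linear <- function(object, X) {
  matrix(object$state$beta, nrow(X), ncol(X), byrow = TRUE,
         dimnames = list(NULL, object$feature_names))
}
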