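#' Prediction matrix constructor
#'
#' Houses the test-set observations `V` and one column of predicted
#' phenotypes `M_i` per model, the inputs to the naive ensemble average and
#' the diversity decomposition.
#'
#' @param predictions numeric matrix, test records x models.
#' @param observed numeric vector of observed trait values.
#' @param model_kinds optional model labels (default from column names).
#' @return a `prediction_matrix`.
#' @export
prediction_matrix <- function(predictions, observed, model_kinds = NULL) {
  predictions <- as.matrix(predictions)
  if (anyNA(predictions) || anyNA(observed))
    stopf("prediction matrix must not contain missing values")
  if (nrow(predictions) != length(observed))
    stopf("predictions and observations disagree on record count")
  if (nrow(predictions) < 1L || ncol(predictions) < 1L)
    stopf("prediction matrix is empty")
  model_kinds <- model_kinds %||% colnames(predictions) %||%
    sprintf("model%d", seq_len(ncol(predictions)))
  colnames(predictions) <- model_kinds
  structure(list(predictions = predictions, observed = as.numeric(observed),
                 model_kinds = model_kinds),
            class = "prediction_matrix")
}

#' Naive equal-weight ensemble average
#'
#' Per-record arithmetic mean of the model predictions (optionally a weighted
#' mean; only uniform weights are studied here, weights exist for API
#' forward-compatibility).
#'
#' @param pm a [prediction_matrix()].
#' @param weights optional non-negative weights, one per model.
#' @return numeric vector of ensemble predictions.
#' @export
ensemble_average <- function(pm, weights = NULL) {
  M <- pm$predictions
  if (is.null(weights)) return(rowMeans(M))
  if (length(weights) != ncol(M) || any(weights < 0) || sum(weights) == 0)
    stopf("weights must be non-negative, one per model, with positive sum")
  as.vector(M %*% (weights / sum(weights)))
}

#' Diversity decomposition of ensemble squared error
#'
#' Per test record, the squared error of the equal-weight ensemble equals the
#' average squared error of the individual models minus the variance of their
#' predictions around the ensemble mean:
#' `(Mbar - V)^2 = sum_i (M_i - V)^2 / N - sum_i (M_i - Mbar)^2 / N`.
#' Each term is then averaged over test records, putting all three on the MSE
#' scale; the identity is preserved by linearity.
#'
#' @param pm a [prediction_matrix()] with at least 2 model columns.
#' @return a `dpt_decomposition`: list with `ensemble_error`, `average_error`,
#'   `diversity`, `n_models`, `n_records`.
#' @export
dpt_decompose <- function(pm) {
  M <- pm$predictions
  if (ncol(M) < 2L) stopf("decomposition needs at least 2 models")
  V <- pm$observed
  Mbar <- rowMeans(M)
  ens <- mean((Mbar - V)^2)
  avg <- mean(rowMeans((M - V)^2))
  div <- mean(rowMeans((M - Mbar)^2))
  structure(list(ensemble_error = ens, average_error = avg, diversity = div,
                 n_models = ncol(M), n_records = nrow(M)),
            class = "dpt_decomposition")
}

#' @export
print.dpt_decomposition <- function(x, ...) {
  cat(sprintf(paste0("Diversity decomposition over %d records, %d models:\n",
                     "  ensemble error  %.4f\n  average error   %.4f\n",
                     "  diversity       %.4f\n"),
              x$n_records, x$n_models, x$ensemble_error, x$average_error,
              x$diversity))
  invisible(x)
}

#' Summarise decompositions across scenarios
#'
#' @param decomps list of [dpt_decompose()] results.
#' @return data frame with one row per term: mean, standard error
#'   (`sd / sqrt(n)`; 0 when a single scenario is supplied) and `n`.
#' @export
aggregate_decompositions <- function(decomps) {
  if (!length(decomps)) stopf("no decompositions to aggregate")
  vals <- vapply(decomps,
                 function(d) c(d$ensemble_error, d$average_error, d$diversity),
                 numeric(3))
  vals <- matrix(vals, nrow = 3)
  n <- ncol(vals)
  data.frame(term = c("ensemble_error", "average_error", "diversity"),
             mean = rowMeans(vals),
             se = if (n > 1) apply(vals, 1, sd) / sqrt(n) else rep(0, 3),
             n = n)
}
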