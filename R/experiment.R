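#' Pearson correlation between predictions and observations
#'
#' @param pred,obs equal-length numeric vectors.
#' @return correlation in [-1, 1]; `NA` (with a warning suppressed upstream)
#'   when either vector is constant — callers exclude and log such records.
#' @export
pearson <- function(pred, obs) {
  if (length(pred) != length(obs)) stopf("length mismatch")
  if (length(pred) < 2L) stopf("need at least 2 records")
  if (sd(pred) == 0 || sd(obs) == 0) return(NA_real_)
  cor(pred, obs)
}

#' Mean squared error
#'
#' @param pred,obs equal-length numeric vectors.
#' @return mean of squared differences; 0 iff identical.
#' @export
mse <- function(pred, obs) {
  if (length(pred) != length(obs)) stopf("length mismatch")
  mean((pred - obs)^2)
}

## ---- model registry -------------------------------------------------------

.model_registry <- new.env(parent = emptyenv())

#' Register or look up model fit functions
#'
#' The registry maps a model kind to a `function(X, y, hyper, seed)` returning
#' an object with a `predict(object, X_new)` method. The six built-in kinds
#' are pre-registered; additional kinds (e.g. fast stubs for orchestration
#' tests) can be added.
#'
#' @param kind model kind tag.
#' @param fit_fn fitting function; omit to look up.
#' @return the fit function, invisibly on registration.
#' @export
register_model <- function(kind, fit_fn) {
  stopifnot(is.function(fit_fn))
  assign(kind, fit_fn, envir = .model_registry)
  invisible(fit_fn)
}

#' @rdname register_model
#' @export
get_model <- function(kind) {
  if (!exists(kind, envir = .model_registry))
    stopf("unknown model kind '%s'", kind)
  get(kind, envir = .model_registry)
}

register_builtin_models <- function() {
  register_model("rrblup", fit_rrblup)
  register_model("bayesb", fit_bayesb)
  register_model("rkhs", fit_rkhs)
  register_model("rf", fit_rf)
  register_model("svr", fit_svr)
  register_model("gat", fit_gat)
  # cheap deterministic stubs for orchestration/bookkeeping tests
  register_model("stub_mean", function(X, y, hyper = list(), seed = 1L)
    linear_model(setNames(rep(0, ncol(X)), colnames(X)), intercept = mean(y)))
  register_model("stub_ols", function(X, y, hyper = list(), seed = 1L) {
    j <- which.max(apply(X, 2, var))
    fit <- stats::lm.fit(cbind(1, X[, j]), y)
    beta <- setNames(rep(0, ncol(X)), colnames(X))
    beta[j] <- fit$coefficients[2]
    linear_model(beta, intercept = fit$coefficients[1])
  })
}

.onLoad <- function(libname, pkgname) register_builtin_models()

#' Scaled-down hyperparameter profiles
#'
#' `"paper"` reproduces the published configuration (12,000 iterations /
#' 2,000 burn-in, 1,000 trees, 50 epochs); `"test"` is the documented desk
#' profile for continuous testing (1,500 / 500, 100 trees, 20 epochs).
#'
#' @param profile `"paper"` or `"test"`.
#' @return named list of per-kind hyperparameter lists.
#' @export
hyper_profile <- function(profile = c("paper", "test")) {
  profile <- match.arg(profile)
  if (profile == "paper")
    list(rrblup = list(), bayesb = list(n_iter = 12000L, burn_in = 2000L),
         rkhs = list(), rf = list(n_trees = 1000L), svr = list(),
         gat = list(epochs = 50L))
  else
    list(rrblup = list(), bayesb = list(n_iter = 1500L, burn_in = 500L),
         rkhs = list(), rf = list(n_trees = 100L), svr = list(),
         gat = list(epochs = 20L))
}

## ---- experiment orchestration ---------------------------------------------

#' Experiment configuration
#'
#' @param populations named list; each element is a named list mapping trait
#'   name to a [concat_environments()] feature table.
#' @param ratios training fractions to evaluate.
#' @param replicates random splits per ratio.
#' @param models character vector of registry kinds.
#' @param hyper named list of per-kind hyperparameter lists.
#' @param master_seed seed from which every cell seed is derived.
#' @param store_predictions keep per-scenario prediction matrices.
#' @return an `experiment_config`.
#' @export
experiment_config <- function(populations, ratios = c(0.8, 0.65, 0.5),
                              replicates = 20L,
                              models = c("rrblup", "bayesb", "rkhs",
                                         "rf", "svr", "gat"),
                              hyper = list(), master_seed = 1L,
                              store_predictions = FALSE) {
  if (any(ratios <= 0) || any(ratios >= 1)) stopf("ratios must lie in (0, 1)")
  if (replicates < 1L) stopf("need at least one replicate")
  if (is.null(names(populations)))
    names(populations) <- sprintf("pop%d", seq_along(populations))
  structure(list(populations = populations, ratios = ratios,
                 replicates = as.integer(replicates), models = models,
                 hyper = hyper, master_seed = master_seed,
                 store_predictions = store_predictions),
            class = "experiment_config")
}

#' Run the full factorial prediction experiment
#'
#' For every (population, trait, ratio, replicate) cell: split the feature
#' table, fit every configured model on the training records, predict the
#' test records, assemble the prediction matrix, and record per-model and
#' ensemble Pearson/MSE plus the diversity decomposition. Cell seeds are
#' derived from the master seed by a stable hash, so reruns are bit-identical
#' and cells are independent of evaluation order. A failing model flags the
#' whole scenario, which is excluded from summaries and logged.
#'
#' @param config an [experiment_config()].
#' @return list with `results` (one row per scenario x model incl.
#'   "ensemble"), `dpt` (per-scenario decomposition terms), `failures`,
#'   and `prediction_matrices` (when requested).
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  res <- list(); dpt <- list(); fails <- list(); pms <- list()
  for (pop in names(config$populations)) {
    for (trait in names(config$populations[[pop]])) {
      ft <- config$populations[[pop]][[trait]]
      for (ratio in config$ratios) {
        for (rep_i in seq_len(config$replicates)) {
          cell <- stable_seed(config$master_seed, pop, trait, ratio, rep_i)
          sp <- split_train_test(ft, split_spec(ratio, rep_i, cell))
          Xtr <- ft$X[sp$train, , drop = FALSE]; ytr <- ft$y[sp$train]
          Xte <- ft$X[sp$test, , drop = FALSE]; yte <- ft$y[sp$test]
          preds <- matrix(NA_real_, length(sp$test), length(config$models),
                          dimnames = list(NULL, config$models))
          failed <- NULL
          for (m in config$models) {
            fit <- try(get_model(m)(Xtr, ytr, config$hyper[[m]] %||% list(),
                                    seed = stable_seed(cell, m)), silent = TRUE)
            p <- if (inherits(fit, "try-error")) fit
                 else try(predict(fit, Xte), silent = TRUE)
            if (inherits(p, "try-error")) {
              failed <- sprintf("%s: %s", m, attr(p, "condition")$message %||%
                                  as.character(p))
              break
            }
            preds[, m] <- p
          }
          key <- data.frame(population = pop, trait = trait, ratio = ratio,
                            replicate = rep_i, stringsAsFactors = FALSE)
          if (!is.null(failed)) {
            fails[[length(fails) + 1L]] <- cbind(key, cause = failed)
            next
          }
          pm <- prediction_matrix(preds, yte)
          ens <- ensemble_average(pm)
          all_preds <- cbind(preds, ensemble = ens)
          for (m in colnames(all_preds)) {
            res[[length(res) + 1L]] <- cbind(
              key, model = m,
              pearson = suppressWarnings(pearson(all_preds[, m], yte)),
              mse = mse(all_preds[, m], yte))
          }
          if (ncol(preds) >= 2L) {
            d <- dpt_decompose(pm)
            dpt[[length(dpt) + 1L]] <- cbind(
              key, ensemble_error = d$ensemble_error,
              average_error = d$average_error, diversity = d$diversity)
          }
          if (config$store_predictions)
            pms[[paste(pop, trait, ratio, rep_i, sep = "/")]] <- pm
        }
      }
    }
  }
  list(results = if (length(res)) do.call(rbind, res) else NULL,
       dpt = if (length(dpt)) do.call(rbind, dpt) else NULL,
       failures = if (length(fails)) do.call(rbind, fails) else NULL,
       prediction_matrices = if (config$store_predictions) pms else NULL)
}

#' Summarise diversity-decomposition terms by trait
#'
#' Pools every scenario of a trait (across populations, ratios and
#' replicates) and reports the mean and standard error of each term.
#'
#' @param dpt the `dpt` data frame from [run_experiment()].
#' @return data frame: trait, term, mean, se, n.
#' @export
dpt_summary <- function(dpt) {
  do.call(rbind, lapply(split(dpt, dpt$trait), function(d) {
    out <- do.call(rbind, lapply(
      c("ensemble_error", "average_error", "diversity"),
      function(tm) data.frame(trait = d$trait[1], term = tm,
                              mean = mean(d[[tm]]),
                              se = if (nrow(d) > 1) sd(d[[tm]]) / sqrt(nrow(d)) else 0,
                              n = nrow(d))))
    rownames(out) <- NULL
    out
  }))
}

#' Percentage of scenarios each model wins
#'
#' Per (ratio, trait, metric), the percentage of scenarios — a scenario is a
#' (population, replicate) pair — in which each model (ensemble included)
#' attains the best value: maximum Pearson correlation or minimum MSE. Exact
#' ties credit every tied model, so a row can exceed 100%. Scenarios whose
#' metric is undefined (constant predictions) are excluded for that metric.
#'
#' @param results the `results` data frame from [run_experiment()].
#' @return data frame: ratio, trait, metric, model, percent, n_scenarios.
#' @export
best_model_percentages <- function(results) {
  if (is.null(results) || !nrow(results)) stopf("empty result table")
  out <- list()
  for (ratio in unique(results$ratio)) for (trait in unique(results$trait)) {
    sub <- results[results$ratio == ratio & results$trait == trait, ]
    if (!nrow(sub)) next
    models <- unique(sub$model)
    for (metric in c("pearson", "mse")) {
      wins <- setNames(numeric(length(models)), models)
      n_scen <- 0L
      for (sc in split(sub, paste(sub$population, sub$replicate))) {
        v <- sc[[metric]]
        if (anyNA(v)) next
        n_scen <- n_scen + 1L
        best <- if (metric == "pearson") max(v) else min(v)
        wins[sc$model[v == best]] <- wins[sc$model[v == best]] + 1L
      }
      if (n_scen == 0L) next
      out[[length(out) + 1L]] <- data.frame(
        ratio = ratio, trait = trait, metric = metric, model = models,
        percent = 100 * as.numeric(wins[models]) / n_scen,
        n_scenarios = n_scen)
    }
  }
  do.call(rbind, out)
}
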