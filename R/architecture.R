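#' Trait architecture constructor
#'
#' Ground truth for a simulated trait: an intercept, additive QTL effects,
#' additive-by-additive epistatic pairs, environment main effects and a target
#' narrow-sense-like heritability used to scale residual noise.
#'
#' @param mu intercept.
#' @param additive_qtl data frame with columns `marker` (column index into the
#'   genotype matrix) and `effect`.
#' @param epistatic_pairs data frame with columns `marker_i`, `marker_j`,
#'   `effect`, `rule` (one of `"product"`, `"complementary"`).
#' @param env_effects numeric vector of per-environment additive main effects.
#' @param target_h2 heritability in (0, 1]: Var(g) / (Var(g) + Var(e)).
#' @return a `trait_architecture`.
#' @export
trait_architecture <- function(mu = 0, additive_qtl = NULL,
                               epistatic_pairs = NULL,
                               env_effects = c(0, 0), target_h2 = 0.8) {
  if (is.null(additive_qtl))
    additive_qtl <- data.frame(marker = integer(), effect = numeric())
  if (is.null(epistatic_pairs))
    epistatic_pairs <- data.frame(marker_i = integer(), marker_j = integer(),
                                  effect = numeric(), rule = character())
  assert_scalar_number(target_h2, "target_h2")
  if (target_h2 <= 0 || target_h2 > 1) stopf("target_h2 must be in (0, 1]")
  if (nrow(epistatic_pairs) &&
      any(epistatic_pairs$marker_i == epistatic_pairs$marker_j))
    stopf("epistatic pairs must involve two distinct markers")
  if (nrow(epistatic_pairs) &&
      !all(epistatic_pairs$rule %in% c("product", "complementary")))
    stopf("unknown epistatic rule tag")
  structure(list(mu = mu, additive_qtl = additive_qtl,
                 epistatic_pairs = epistatic_pairs,
                 env_effects = as.numeric(env_effects),
                 target_h2 = target_h2),
            class = "trait_architecture")
}

#' Draw a random trait architecture
#'
#' QTL positions are sampled without replacement from the map (additive QTL
#' and epistatic-pair members are all distinct markers); effect sizes are
#' N(0, effect_scale^2). Epistatic pairs use the additive-by-additive
#' `"product"` rule by default: effect * (x_i - 1) * (x_j - 1).
#'
#' @inheritParams trait_architecture
#' @param map a [marker_map()].
#' @param n_additive_qtl,n_epistatic_pairs counts of causal terms.
#' @param effect_scale SD of drawn effects.
#' @param epistatic_scale SD of epistatic effects (defaults to `effect_scale`).
#' @param rule epistatic rule tag for all pairs.
#' @param seed RNG seed.
#' @param mu intercept (default 0).
#' @return a [trait_architecture()].
#' @export
assign_trait_architecture <- function(map, n_additive_qtl, n_epistatic_pairs,
                                      effect_scale = 1,
                                      env_effect_sizes = c(0, 1),
                                      target_h2 = 0.8, seed = 1L,
                                      epistatic_scale = effect_scale,
                                      rule = "product", mu = 0) {
  map <- validate_marker_map(as.data.frame(map))
  need <- n_additive_qtl + 2L * n_epistatic_pairs
  if (need > nrow(map))
    stopf("architecture needs %d distinct markers but the map has %d",
          need, nrow(map))
  with_seed(seed, {
    idx <- if (need > 0) sample.int(nrow(map), need) else integer()
    add <- data.frame(marker = idx[seq_len(n_additive_qtl)],
                      effect = rnorm(n_additive_qtl, 0, effect_scale))
    rest <- idx[-seq_len(n_additive_qtl)]
    epi <- data.frame(
      marker_i = rest[seq_len(n_epistatic_pairs) * 2L - 1L],
      marker_j = rest[seq_len(n_epistatic_pairs) * 2L],
      effect = rnorm(n_epistatic_pairs, 0, epistatic_scale),
      rule = rep(rule, n_epistatic_pairs))
    trait_architecture(mu = mu, additive_qtl = add, epistatic_pairs = epi,
                       env_effects = env_effect_sizes, target_h2 = target_h2)
  })
}

#' True genetic values under an architecture
#'
#' @param geno a [genotype_matrix()] (no missing calls).
#' @param arch a [trait_architecture()].
#' @return numeric vector, one genetic value per RIL.
#' @export
genetic_values <- function(geno, arch) {
  X <- geno$dosages
  if (anyNA(X)) stopf("genetic values need a complete genotype matrix")
  g <- rep(arch$mu, nrow(X))
  aq <- arch$additive_qtl
  if (nrow(aq)) {
    if (any(aq$marker < 1 | aq$marker > ncol(X))) stopf("QTL index out of range")
    g <- g + as.vector(X[, aq$marker, drop = FALSE] %*% aq$effect)
  }
  ep <- arch$epistatic_pairs
  for (k in seq_len(nrow(ep))) {
    xi <- X[, ep$marker_i[k]]; xj <- X[, ep$marker_j[k]]
    term <- switch(ep$rule[k],
                   product = (xi - 1) * (xj - 1),
                   complementary = as.numeric(xi > 0 & xj > 0),
                   stopf("unknown epistatic rule '%s'", ep$rule[k]))
    g <- g + ep$effect[k] * term
  }
  unname(g)
}
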