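#' Simulate phenotype records
#'
#' Computes each line's genetic value g under the architecture, then emits one
#' record per (RIL, environment) with value
#' `g + env_effect[environment] + e`, where the residual SD is chosen so that
#' Var(g) / (Var(g) + Var(e)) equals the architecture's `target_h2` across the
#' simulated population. With `target_h2 = 1` (or a zero-variance g) the
#' residual is exactly zero. Environment effects are additive main effects
#' only: no genotype-by-environment interaction is simulated.
#'
#' @param geno a [genotype_matrix()] with no missing calls.
#' @param arch a [trait_architecture()].
#' @param environments number of environments (must not exceed
#'   `length(arch$env_effects)`).
#' @param trait trait name recorded in the table.
#' @param seed RNG seed.
#' @return a `phenotype_table`: data frame with columns `ril_id`, `env`
#'   (factor "E1", "E2", ...), `trait`, `value` and the ground-truth genetic
#'   value `g`.
#' @export
simulate_phenotypes <- function(geno, arch, environments = 2L,
                                trait = "trait", seed = 1L) {
  if (arch$target_h2 <= 0) stopf("target_h2 must be positive")
  if (environments > length(arch$env_effects))
    stopf("architecture provides %d environment effects but %d environments requested",
          length(arch$env_effects), environments)
  g <- genetic_values(geno, arch)
  var_g <- var(g) * (length(g) - 1) / length(g)  # population variance
  var_e <- var_g * (1 - arch$target_h2) / arch$target_h2
  n <- length(g)
  with_seed(seed, {
    recs <- do.call(rbind, lapply(seq_len(environments), function(ev) {
      data.frame(ril_id = rownames(geno$dosages),
                 env = sprintf("E%d", ev),
                 trait = trait,
                 value = g + arch$env_effects[ev] + rnorm(n, 0, sqrt(var_e)),
                 g = g,
                 stringsAsFactors = FALSE)
    }))
    phenotype_table(recs)
  })
}

#' Phenotype table constructor
#'
#' @param records data frame with columns `ril_id`, `env`, `trait`, `value`
#'   (and optionally ground truth `g`).
#' @return a `phenotype_table` (also a `data.frame`).
#' @export
phenotype_table <- function(records) {
  need <- c("ril_id", "env", "trait", "value")
  if (!all(need %in% names(records)))
    stopf("phenotype table needs columns %s", paste(need, collapse = ", "))
  if (anyDuplicated(records[, c("ril_id", "env", "trait")]))
    stopf("duplicate (ril_id, env, trait) record")
  class(records) <- c("phenotype_table", "data.frame")
  records
}

#' Inject missing marker calls
#'
#' Masks entries independently at `overall_rate`. In addition, a fraction of
#' SNP columns is given an elevated missingness rate (`high_rate`, default
#' 0.2, i.e. above the conventional 10% filter threshold) so that the
#' missingness filter has columns to remove.
#'
#' @param geno a [genotype_matrix()].
#' @param overall_rate per-entry missing probability for ordinary columns.
#' @param high_missing_snp_fraction fraction of columns given `high_rate`.
#' @param high_rate elevated per-entry missing probability.
#' @param seed RNG seed.
#' @return a [genotype_matrix()] with `NA`s inserted.
#' @export
inject_missing <- function(geno, overall_rate, high_missing_snp_fraction = 0,
                           high_rate = 0.2, seed = 1L) {
  for (r in c(overall_rate, high_missing_snp_fraction, high_rate))
    assert_scalar_number(r, "rate", lower = 0, upper = 1)
  X <- geno$dosages
  with_seed(seed, {
    col_rate <- rep(overall_rate, ncol(X))
    n_high <- floor(high_missing_snp_fraction * ncol(X))
    if (n_high > 0)
      col_rate[sample.int(ncol(X), n_high)] <- high_rate
    mask <- matrix(runif(length(X)), nrow(X)) <
      matrix(col_rate, nrow(X), ncol(X), byrow = TRUE)
    X[mask] <- NA
    genotype_matrix(X, geno$map)
  })
}
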