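# Shared fixtures and independent oracles. Everything is generated in code;
# oracle implementations here are deliberately naive (enumeration, direct
# formulas) and independent of the package's computational paths.

# small simulated population reused across model tests
sim_population <- function(n_ril = 200, n_chrom = 2, markers_per_chrom = 30,
                           seed = 1) {
  map <- simulate_marker_map(n_chrom, markers_per_chrom, 5e7, 120,
                             seed = seed)
  geno <- simulate_ril_population(map, n_ril, seed = seed + 1)
  list(map = map, geno = geno)
}

# simulate a single-environment additive trait and return a ready design
sim_trait_design <- function(pop, qtl, effects, h2 = 0.8, seed = 1) {
  arch <- trait_architecture(
    additive_qtl = data.frame(marker = qtl, effect = effects),
    env_effects = c(0, 0), target_h2 = h2)
  ph <- simulate_phenotypes(pop$geno, arch, environments = 1, seed = seed)
  list(X = pop$geno$dosages, y = ph$value, g = ph$g, arch = arch)
}

# brute-force Shapley enumeration over all feature subsets (<= ~8 features),
# marginalising absent features over the full background set
exact_shapley <- function(f, x, background) {
  p <- length(x)
  subsets <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), p)))
  vals <- apply(subsets, 1, function(S) {
    M <- background
    if (any(S)) M[, S] <- matrix(x[S], nrow(background), sum(S), byrow = TRUE)
    colnames(M) <- colnames(background)
    mean(f(M))
  })
  key <- subsets %*% 2^(seq_len(p) - 1)
  phi <- numeric(p)
  for (i in seq_len(p)) {
    for (r in seq_len(nrow(subsets))) {
      S <- subsets[r, ]
      if (S[i]) next
      s <- sum(S)
      w <- factorial(s) * factorial(p - s - 1) / factorial(p)
      r1 <- match(key[r] + 2^(i - 1), key)
      phi[i] <- phi[i] + w * (vals[r1] - vals[r])
    }
  }
  phi
}

# direct-formula Pearson correlation (oracle for pearson())
pearson_oracle <- function(a, b) {
  n <- length(a)
  num <- sum(a * b) - n * mean(a) * mean(b)
  den <- sqrt((sum(a^2) - n * mean(a)^2) * (sum(b^2) - n * mean(b)^2))
  num / den
}

# tiny complete feature table for orchestration tests
stub_feature_table <- function(n_ril = 10, p = 4, seed = 99) {
  withr::with_seed(seed, {
    X <- matrix(rbinom(n_ril * p, 2, 0.4), n_ril)
    colnames(X) <- sprintf("m%d", seq_len(p))
    map <- marker_map(colnames(X), 1, seq_len(p) * 1000, seq_len(p))
    geno <- genotype_matrix(X, map)
    arch <- trait_architecture(
      additive_qtl = data.frame(marker = 1, effect = 1),
      env_effects = c(0, 0.5), target_h2 = 0.8)
    ph <- simulate_phenotypes(geno, arch, seed = seed)
    concat_environments(ph, geno)
  })
}
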