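# Simulator: marker maps, RIL populations, architectures, phenotypes,
# missingness injection.

test_that("simulate_marker_map builds sorted maps of the requested size", {
  m <- simulate_marker_map(1, 10, 1e6, 100, seed = 1)
  expect_s3_class(m, "marker_map")
  expect_equal(nrow(m), 10)
  expect_true(all(diff(m$position_bp) > 0))
  expect_true(all(diff(m$position_cM) >= 0))

  m5 <- simulate_marker_map(5, 60, 3e8, 150, seed = 7)
  expect_equal(nrow(m5), 300)
  expect_equal(as.vector(table(m5$chromosome)), rep(60, 5))

  expect_identical(simulate_marker_map(2, 10, 1e6, 50, seed = 3),
                   simulate_marker_map(2, 10, 1e6, 50, seed = 3))
  expect_error(simulate_marker_map(1, 0, 1e6, 100), "positive")
  expect_error(simulate_marker_map(1, 10, -5, 100), "positive")
})

test_that("BC1S4 RIL populations satisfy Mendelian expectations", {
  map <- simulate_marker_map(5, 60, 6e7, 150, seed = 2)
  g <- simulate_ril_population(map, 500, seed = 3)
  expect_equal(dim(g$dosages), c(500, 300))
  expect_false(anyNA(g$dosages))
  # donor allele frequency: 0.25 expected for BC1-derived selfed lines
  expect_lt(abs(mean(g$dosages) / 2 - 0.25), 0.03)
  # residual heterozygosity: 0.5 * (1/2)^4 after four selfings from BC1
  expect_lt(abs(mean(g$dosages == 1) - 0.03125), 0.01)
})

test_that("linkage decays with map distance and vanishes across chromosomes", {
  map <- simulate_marker_map(2, 40, 5e7, 120, seed = 4)
  g <- simulate_ril_population(map, 500, seed = 5)
  d <- g$dosages
  r_adjacent <- mean(vapply(1:39, function(j) cor(d[, j], d[, j + 1]),
                            numeric(1)))
  r_distant <- mean(vapply(1:10, function(j) cor(d[, j], d[, j + 25]),
                           numeric(1)))
  r_cross <- abs(cor(d[, 5], d[, 45]))
  expect_gt(r_adjacent, r_distant)
  expect_lt(r_cross, 0.1)
})

test_that("RIL simulation is reproducible and validates inputs", {
  map <- simulate_marker_map(1, 5, 1e6, 80, seed = 6)
  expect_identical(simulate_ril_population(map, 20, seed = 9),
                   simulate_ril_population(map, 20, seed = 9))
  expect_error(simulate_ril_population(map[0, ], 5), "empty")
})

test_that("trait architectures respect counts, distinctness and determinism", {
  map <- simulate_marker_map(2, 20, 1e7, 90, seed = 1)
  a <- assign_trait_architecture(map, 3, 3, seed = 11)
  expect_equal(nrow(a$additive_qtl), 3)
  expect_equal(nrow(a$epistatic_pairs), 3)
  expect_true(all(a$epistatic_pairs$marker_i != a$epistatic_pairs$marker_j))
  idx <- c(a$additive_qtl$marker, a$epistatic_pairs$marker_i,
           a$epistatic_pairs$marker_j)
  expect_false(anyDuplicated(idx) > 0)
  expect_identical(a, assign_trait_architecture(map, 3, 3, seed = 11))
  expect_error(assign_trait_architecture(map, 100, 0), "distinct markers")
  # no QTL at all: zero genetic variance
  g <- simulate_ril_population(map, 30, seed = 2)
  null_arch <- assign_trait_architecture(map, 0, 0, target_h2 = 1, seed = 1)
  expect_equal(var(genetic_values(g, null_arch)), 0)
})

test_that("phenotypes follow the closed-form genetic values when noiseless", {
  map <- marker_map(c("a", "b"), 1, c(100, 200), c(0, 1))
  geno <- genotype_matrix(rbind(c(2, 0), c(1, 2), c(0, 1)), map)
  arch <- trait_architecture(
    mu = 0, additive_qtl = data.frame(marker = 1, effect = 2),
    env_effects = c(0, 0), target_h2 = 1)
  ph <- simulate_phenotypes(geno, arch, environments = 1, seed = 1)
  expect_equal(ph$value, c(4, 2, 0))

  # no QTL, h2 -> 1: every record equals the intercept
  arch0 <- trait_architecture(mu = 5, env_effects = c(0, 0), target_h2 = 1)
  ph0 <- simulate_phenotypes(geno, arch0, seed = 1)
  expect_true(all(ph0$value == 5))

  # epistatic closed forms
  archp <- trait_architecture(
    epistatic_pairs = data.frame(marker_i = 1, marker_j = 2, effect = 3,
                                 rule = "product"),
    env_effects = c(0, 0), target_h2 = 1)
  expect_equal(genetic_values(geno, archp), c(-3, 0, 0))
  archc <- trait_architecture(
    epistatic_pairs = data.frame(marker_i = 1, marker_j = 2, effect = 3,
                                 rule = "complementary"),
    env_effects = c(0, 0), target_h2 = 1)
  expect_equal(genetic_values(geno, archc), c(0, 3, 0))
})

test_that("residual scaling hits the target heritability", {
  pop <- sim_population(500, 2, 40, seed = 21)
  arch <- assign_trait_architecture(pop$map, 5, 0, env_effect_sizes = c(0, 0),
                                    target_h2 = 0.7, seed = 22)
  ph <- simulate_phenotypes(pop$geno, arch, seed = 23)
  expect_lt(abs(var(ph$g) / var(ph$value) - 0.7), 0.05)
  expect_error(
    simulate_phenotypes(pop$geno,
                        trait_architecture(target_h2 = 0.5), environments = 3),
    "environment")
  expect_error(trait_architecture(target_h2 = 0), "target_h2")
})

test_that("environment effects are additive main effects", {
  map <- marker_map("a", 1, 100, 0)
  geno <- genotype_matrix(matrix(c(0, 2), 2, 1), map)
  arch <- trait_architecture(
    additive_qtl = data.frame(marker = 1, effect = 1),
    env_effects = c(0, 10), target_h2 = 1)
  ph <- simulate_phenotypes(geno, arch, seed = 1)
  v <- ph$value
  expect_equal(v[ph$env == "E2"] - v[ph$env == "E1"], c(10, 10))
})

test_that("inject_missing masks at the requested rate, reproducibly", {
  pop <- sim_population(100, 1, 50, seed = 31)
  g0 <- inject_missing(pop$geno, 0, 0, seed = 1)
  expect_identical(g0$dosages, pop$geno$dosages)

  pop2 <- sim_population(500, 2, 30, seed = 32)
  g5 <- inject_missing(pop2$geno, 0.05, 0, seed = 2)
  expect_lt(abs(mean(is.na(g5$dosages)) - 0.05), 0.01)
  expect_identical(inject_missing(pop2$geno, 0.05, 0, seed = 2)$dosages,
                   g5$dosages)

  # elevated columns exceed the 10% filter threshold
  gh <- inject_missing(pop2$geno, 0.02, 0.2, high_rate = 0.25, seed = 3)
  frac <- colMeans(is.na(gh$dosages))
  expect_gte(sum(frac > 0.10), floor(0.2 * ncol(gh$dosages)) * 0.5)
  expect_error(inject_missing(pop$geno, 1.5), "rate")
})
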