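# Cleaning chain: missingness filter, both imputation methods, LD pruning,
# environment concatenation, train/test splits.

make_geno <- function(dos, bp = NULL, chrom = 1) {
  p <- ncol(dos)
  if (is.null(bp)) bp <- seq_len(p) * 1000
  genotype_matrix(dos, marker_map(sprintf("m%d", seq_len(p)), chrom, bp,
                                  bp / 1e4))
}

test_that("missingness filter keeps exactly 10% and drops more", {
  dos <- matrix(rep(0:1, 40), 20, 4)
  dos[1:2, 1] <- NA   # 10% -> kept
  dos[1:3, 2] <- NA   # 15% -> dropped
  g <- filter_missing_snps(make_geno(dos), max_missing = 0.10)
  expect_equal(colnames(g$dosages), c("m1", "m3", "m4"))

  # no missing anywhere: identity
  g2 <- make_geno(matrix(rbinom(40, 2, .5), 10, 4))
  expect_identical(filter_missing_snps(g2)$dosages, g2$dosages)

  # constructed fixture: 30 of 300 columns seeded with 20% missingness
  pop <- sim_population(50, 5, 60, seed = 41)
  dos3 <- pop$geno$dosages
  bad <- seq(1, 300, by = 10)
  dos3[1:10, bad] <- NA
  g3 <- filter_missing_snps(genotype_matrix(dos3, pop$map))
  expect_equal(ncol(g3$dosages), 270)

  all_bad <- matrix(NA, 10, 2)
  expect_error(filter_missing_snps(make_geno(all_bad)), "all SNPs")
})

test_that("modal imputation fills with the most frequent dosage, low tie", {
  dos <- cbind(c(0, 0, 2, NA), c(0, 0, 2, 2))
  g <- impute_most_frequent(make_geno(dos))
  expect_equal(g$dosages[4, 1], 0)

  dos_tie <- cbind(c(0, 0, 2, 2, NA), c(1, 1, 1, 1, 1))
  expect_equal(impute_most_frequent(make_geno(dos_tie))$dosages[5, 1], 0)

  # random fixture: no missing left, observed entries untouched, idempotent
  pop <- sim_population(60, 1, 40, seed = 42)
  gm <- inject_missing(pop$geno, 0.08, 0, seed = 7)
  obs <- !is.na(gm$dosages)
  gi <- impute_most_frequent(gm)
  expect_false(anyNA(gi$dosages))
  expect_identical(gi$dosages[obs], gm$dosages[obs])
  expect_identical(impute_most_frequent(gi)$dosages, gi$dosages)

  expect_error(impute_most_frequent(make_geno(cbind(c(NA, NA), c(0, 1)))),
               "filter_missing_snps")
})

test_that("flanking imputation follows the agreement/closest/end rules", {
  bp <- c(100, 200, 250, 5000, 6000)
  dos <- rbind(R1 = c(2, NA, 2, 0, 0),    # flanks agree -> 2
               R2 = c(0, NA, 2, 2, 2),    # disagree; m3 is closer -> 2
               R3 = c(NA, 1, 1, 1, 1),    # left end: single flank -> 1
               R4 = c(0, 0, 0, 0, NA),    # right end: single flank -> 0
               R5 = c(NA, NA, NA, NA, NA))
  out <- impute_flanking(make_geno(dos, bp))
  expect_equal(out$removed_ril_ids, "R5")
  got <- out$geno$dosages
  expect_equal(unname(got["R1", 2]), 2)
  expect_equal(unname(got["R2", 2]), 2)
  expect_equal(unname(got["R3", 1]), 1)
  expect_equal(unname(got["R4", 5]), 0)
  # observed calls untouched; idempotent
  expect_equal(unname(got["R2", c(1, 3:5)]), c(0, 2, 2, 2))
  expect_identical(impute_flanking(out$geno)$geno$dosages, got)
})

test_that("flanking equidistant ties take the left flank", {
  bp <- c(100, 200, 300)
  dos <- rbind(R1 = c(2, NA, 0))
  out <- impute_flanking(make_geno(dos, bp))
  expect_equal(unname(out$geno$dosages[1, 2]), 2)
})

test_that("LD pruning removes duplicates and is a fixed point", {
  withr::with_seed(8, {
    a <- rbinom(200, 2, .5)
    b <- rbinom(200, 2, .5)
    g <- make_geno(cbind(a, a, 2 - a, b), bp = c(100, 200, 300, 4000))
  })
  pan <- ld_prune(g, r2_threshold = 0.8)
  # exactly one survivor among the three perfectly correlated columns
  expect_equal(sum(pan$kept %in% 1:3), 1)
  expect_true(4 %in% pan$kept)
  expect_equal(nrow(pan$removed), 2)
  expect_true(all(pan$removed$r2 > 1 - 1e-12))
  # pruning the pruned panel removes nothing
  pan2 <- ld_prune(apply_pruning(g, pan))
  expect_equal(nrow(pan2$removed), 0)
})

test_that("independent columns survive pruning; zero-variance kept", {
  withr::with_seed(9, {
    dos <- matrix(rbinom(500 * 10, 2, .5), 500, 10)
    dos[, 10] <- 1  # constant column
    g <- make_geno(dos, bp = seq_len(10) * 100)
  })
  pan <- ld_prune(g)
  expect_equal(pan$kept, 1:10)
})

test_that("pruning respects the bp window and marker count never grows", {
  withr::with_seed(10, {
    a <- rbinom(300, 2, .5)
    # duplicate columns 40 kb apart: outside a 30 kb window, both kept
    g <- make_geno(cbind(a, a), bp = c(1000, 41000))
  })
  expect_equal(ld_prune(g)$kept, 1:2)
  # same duplicate inside the window: one removed
  g2 <- genotype_matrix(g$dosages,
                        marker_map(c("m1", "m2"), 1, c(1000, 21000),
                                   c(0.1, 2.1)))
  expect_equal(length(ld_prune(g2)$kept), 1)
})

test_that("environment concatenation builds one row per record", {
  pop <- sim_population(25, 1, 8, seed = 43)
  arch <- assign_trait_architecture(pop$map, 2, 0, seed = 44)
  ph <- simulate_phenotypes(pop$geno, arch, seed = 45)
  ft <- concat_environments(ph, pop$geno)
  expect_equal(dim(ft$X), c(50, 9))
  expect_equal(colnames(ft$X)[9], ".env")
  # same RIL in both environments: identical markers, different indicator
  r1 <- which(ft$records$ril_id == ft$records$ril_id[1])
  expect_equal(ft$X[r1[1], 1:8], ft$X[r1[2], 1:8])
  expect_equal(sort(ft$X[r1, 9]), c(0, 1))
  # missing one environment: single row, no error
  ph_sub <- phenotype_table(ph[-1, ])
  ft2 <- concat_environments(ph_sub, pop$geno)
  expect_equal(nrow(ft2$X), 49)
  # unknown RIL id
  ph_bad <- ph
  ph_bad$ril_id[1] <- "nope"
  expect_error(concat_environments(phenotype_table(ph_bad), pop$geno),
               "unknown RILs")
})

test_that("train/test splits are exact partitions, reproducibly", {
  ft <- stub_feature_table(5, 3)  # 10 records
  sp <- split_train_test(ft, split_spec(0.8, 1, 7))
  expect_length(sp$train, 8)
  expect_length(sp$test, 2)
  expect_identical(split_train_test(ft, split_spec(0.8, 1, 7)), sp)
  expect_false(identical(split_train_test(ft, split_spec(0.8, 2, 7)), sp))
  for (frac in c(0.8, 0.65, 0.5)) for (rep_i in 1:5) {
    s <- split_train_test(ft, split_spec(frac, rep_i, 11))
    expect_equal(sort(c(s$train, s$test)), 1:10)
    expect_length(intersect(s$train, s$test), 0)
    expect_length(s$train, round(frac * 10))
  }
  expect_error(split_spec(0), "train_fraction")
  expect_error(split_train_test(ft, split_spec(0.999)), "empty train or test")
})
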