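#' Drop SNPs with excess missingness
#'
#' Removes columns whose missing fraction is strictly greater than
#' `max_missing` ("more than 10%" semantics: exactly 10% is kept). Column
#' order is preserved.
#'
#' @param geno a [genotype_matrix()].
#' @param max_missing maximum tolerated missing fraction.
#' @return a filtered [genotype_matrix()].
#' @export
filter_missing_snps <- function(geno, max_missing = 0.10) {
  X <- geno$dosages
  if (ncol(X) == 0L) stopf("genotype matrix is empty")
  frac <- colMeans(is.na(X))
  keep <- frac <= max_missing
  if (!any(keep)) stopf("all SNPs exceed the missingness threshold")
  genotype_matrix(X[, keep, drop = FALSE], geno$map[keep, , drop = FALSE])
}

#' Impute missing calls with the most frequent dosage
#'
#' Each column's missing entries are replaced by that column's modal dosage;
#' ties are broken toward the lower dosage. Observed entries are untouched.
#'
#' @param geno a [genotype_matrix()].
#' @return an imputed [genotype_matrix()] with no missing calls.
#' @export
impute_most_frequent <- function(geno) {
  X <- geno$dosages
  for (j in seq_len(ncol(X))) {
    miss <- is.na(X[, j])
    if (!any(miss)) next
    if (all(miss))
      stopf("column %s is fully missing; run filter_missing_snps() first",
            colnames(X)[j])
    counts <- tabulate(X[!miss, j] + 1L, nbins = 3L)
    X[miss, j] <- which.max(counts) - 1L  # which.max takes the first (lowest) tie
  }
  genotype_matrix(X, geno$map)
}

#' Impute missing calls from flanking markers
#'
#' Within each RIL and chromosome, a missing call takes the shared genotype
#' when the nearest non-missing flanking markers on both sides agree; when
#' they disagree, the genotype of the physically (bp) closest flank is used
#' (equidistant ties take the left flank). At chromosome ends the single
#' available flank is used. RILs with an entirely missing chromosome cannot be
#' imputed and are removed.
#'
#' @param geno a [genotype_matrix()].
#' @param map optional map (defaults to the one carried by `geno`).
#' @return list with elements `geno` (imputed [genotype_matrix()]) and
#'   `removed_ril_ids` (character).
#' @export
impute_flanking <- function(geno, map = geno$map) {
  map <- validate_marker_map(as.data.frame(map))
  X <- geno$dosages
  chroms <- split(seq_len(nrow(map)), map$chromosome)
  removed <- logical(nrow(X))
  for (cols in chroms) {
    bp <- map$position_bp[cols]
    for (r in seq_len(nrow(X))) {
      x <- X[r, cols]
      miss <- which(is.na(x))
      if (!length(miss)) next
      obs <- which(!is.na(x))
      if (!length(obs)) { removed[r] <- TRUE; next }
      left <- obs[findInterval(miss, obs)]            # 0 -> NA index
      pos_r <- findInterval(miss, obs, left.open = TRUE) + 1L
      right <- obs[ifelse(pos_r > length(obs), NA, pos_r)]
      fill <- numeric(length(miss))
      for (k in seq_along(miss)) {
        l <- left[k]; rt <- right[k]
        fill[k] <- if (is.na(l)) x[rt]
        else if (is.na(rt)) x[l]
        else if (x[l] == x[rt]) x[l]
        else if (bp[miss[k]] - bp[l] <= bp[rt] - bp[miss[k]]) x[l]
        else x[rt]
      }
      X[r, cols[miss]] <- fill
    }
  }
  out <- genotype_matrix(X[!removed, , drop = FALSE], map,
                         ril_ids = rownames(X)[!removed])
  list(geno = out, removed_ril_ids = rownames(X)[removed])
}

#' Windowed LD pruning
#'
#' Within each chromosome a window `window_bp` wide is anchored at the
#' left-most unpruned marker and advanced `step` markers at a time. Within a
#' window, while any surviving pair of markers has squared Pearson
#' correlation of dosages above `r2_threshold`, the pair member with the lower
#' minor-allele frequency is removed (ties drop the later-position marker).
#' Passes repeat until no removal occurs, so pruning the pruned panel again
#' removes nothing. Zero-variance columns cannot enter a correlation pair and
#' are always kept.
#'
#' @param geno a complete (imputed) [genotype_matrix()].
#' @param map optional map override.
#' @param r2_threshold prune pairs with r^2 strictly above this value.
#' @param window_bp window width in base pairs.
#' @param step markers the window anchor advances per step.
#' @return a `pruned_panel`: list with `kept` (sorted column indices),
#'   `removed` (data frame: `removed`, `partner`, `r2`) and `map`.
#' @export
ld_prune <- function(geno, map = geno$map, r2_threshold = 0.8,
                     window_bp = 30000, step = 5L) {
  X <- geno$dosages
  if (anyNA(X)) stopf("ld_prune needs an imputed genotype matrix")
  map <- validate_marker_map(as.data.frame(map))
  alive <- rep(TRUE, ncol(X))
  maf <- apply(X, 2, function(x) { f <- mean(x) / 2; min(f, 1 - f) })
  log_rows <- list()
  for (cols in split(seq_len(ncol(X)), map$chromosome)) {
    bp <- map$position_bp[cols]
    repeat {
      removed_this_pass <- FALSE
      anchor <- 1L
      while (anchor <= length(cols)) {
        live <- which(alive[cols])
        live <- live[live >= anchor]
        if (!length(live)) break
        a <- min(live)
        win <- live[bp[live] < bp[a] + window_bp]
        if (length(win) >= 2L) {
          sub <- X[, cols[win], drop = FALSE]
          sds <- apply(sub, 2, sd)
          ok <- sds > 0
          while (sum(ok) >= 2L) {
            r2 <- suppressWarnings(cor(sub[, ok, drop = FALSE]))^2
            r2[!upper.tri(r2)] <- 0
            if (max(r2, na.rm = TRUE) <= r2_threshold) break
            ij <- which(r2 == max(r2, na.rm = TRUE), arr.ind = TRUE)[1, ]
            pair <- win[ok][ij]                       # chrom-local indices
            gi <- cols[pair]                          # global column indices
            drop_local <- if (maf[gi[1]] < maf[gi[2]]) 1L
                          else if (maf[gi[1]] > maf[gi[2]]) 2L
                          else 2L                     # tie: later position
            keep_local <- 3L - drop_local
            alive[gi[drop_local]] <- FALSE
            removed_this_pass <- TRUE
            log_rows[[length(log_rows) + 1L]] <- data.frame(
              removed = colnames(X)[gi[drop_local]],
              partner = colnames(X)[gi[keep_local]],
              r2 = max(r2, na.rm = TRUE))
            ok[match(pair[drop_local], win)] <- FALSE
          }
        }
        anchor <- anchor + step
      }
      if (!removed_this_pass) break
    }
  }
  removed <- if (length(log_rows)) do.call(rbind, log_rows)
             else data.frame(removed = character(), partner = character(),
                             r2 = numeric())
  structure(list(kept = which(alive), removed = removed, map = map),
            class = "pruned_panel")
}

#' Subset a genotype matrix to a pruned panel
#'
#' @param geno a [genotype_matrix()].
#' @param panel a `pruned_panel` from [ld_prune()].
#' @return the pruned [genotype_matrix()].
#' @export
apply_pruning <- function(geno, panel) {
  genotype_matrix(geno$dosages[, panel$kept, drop = FALSE],
                  geno$map[panel$kept, , drop = FALSE])
}

#' Concatenate environments into one feature table
#'
#' Builds one feature row per phenotype record: the RIL's marker dosages plus
#' a binary environment indicator column named `".env"` (0 for the first
#' environment level, 1 for the second). The response is the record's trait
#' value.
#'
#' @param pheno a [phenotype_table()] for a single trait.
#' @param geno a complete [genotype_matrix()].
#' @return a `feature_table`: list with `X` (records x (p+1) matrix), `y`,
#'   `records` (data frame `ril_id`, `env`), `trait` and `marker_ids`.
#' @export
concat_environments <- function(pheno, geno) {
  if (length(unique(pheno$trait)) > 1L)
    stopf("feature table is per trait; got %d traits", length(unique(pheno$trait)))
  idx <- match(pheno$ril_id, rownames(geno$dosages))
  if (anyNA(idx))
    stopf("phenotype records reference unknown RILs: %s",
          paste(unique(pheno$ril_id[is.na(idx)]), collapse = ", "))
  levs <- sort(unique(as.character(pheno$env)))
  if (length(levs) > 2L) stopf("at most 2 environment levels supported")
  X <- cbind(geno$dosages[idx, , drop = FALSE],
             .env = as.numeric(as.character(pheno$env) == levs[min(2L, length(levs))]))
  rownames(X) <- NULL
  structure(list(X = X, y = pheno$value,
                 records = data.frame(ril_id = pheno$ril_id,
                                      env = as.character(pheno$env),
                                      stringsAsFactors = FALSE),
                 trait = pheno$trait[1], marker_ids = colnames(geno$dosages)),
            class = "feature_table")
}

#' Train/test split specification
#'
#' @param train_fraction fraction of records in the training set (0 < f < 1).
#' @param replicate replicate index (varies the split at a fixed seed).
#' @param seed base RNG seed.
#' @export
split_spec <- function(train_fraction = 0.8, replicate = 1L, seed = 1L) {
  assert_scalar_number(train_fraction, "train_fraction")
  if (train_fraction <= 0 || train_fraction >= 1)
    stopf("train_fraction must be in (0, 1)")
  structure(list(train_fraction = train_fraction,
                 replicate = as.integer(replicate), seed = as.integer(seed)),
            class = "split_spec")
}

#' Random record-level train/test partition
#'
#' Draws `round(train_fraction * n)` training records uniformly at random;
#' the remainder is the test set. Deterministic given the spec's
#' (seed, replicate). Records (not RILs) are split, so the two environment
#' records of one RIL may straddle the partition, matching a
#' concatenate-then-split workflow.
#'
#' @param feature_table a [concat_environments()] result (or anything with a
#'   row count via `nrow(x$X)`).
#' @param spec a [split_spec()].
#' @return list with integer vectors `train` and `test`.
#' @export
split_train_test <- function(feature_table, spec) {
  n <- nrow(feature_table$X)
  if (is.null(n) || n == 0L) stopf("feature table is empty")
  n_train <- round(spec$train_fraction * n)
  if (n_train == 0L || n_train == n)
    stopf("split leaves an empty train or test set (n = %d, fraction = %g)",
          n, spec$train_fraction)
  train <- with_seed(stable_seed(spec$seed, "split", spec$replicate),
                     sort(sample.int(n, n_train)))
  list(train = train, test = setdiff(seq_len(n), train))
}
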