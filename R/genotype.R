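#' Genotype matrix constructor
#'
#' Holds a RIL x SNP dosage matrix coded as the count of donor-parent
#' (e.g. teosinte) alleles: 0 = homozygous recurrent parent, 1 = heterozygous,
#' 2 = homozygous donor. Missing calls are `NA`. Column order must match the
#' accompanying marker map.
#'
#' @param dosages integer matrix (RIL x SNP) with values in \{0, 1, 2, NA\}.
#' @param map a [marker_map()] with one row per column of `dosages`.
#' @param ril_ids optional RIL identifiers (default from rownames or R1..Rn).
#' @return a `genotype_matrix`: list with elements `dosages` (named matrix)
#'   and `map`.
#' @export
genotype_matrix <- function(dosages, map, ril_ids = NULL) {
  dosages <- as.matrix(dosages)
  map <- validate_marker_map(as.data.frame(map))
  if (ncol(dosages) != nrow(map))
    stopf("dosage matrix has %d columns but map has %d markers",
          ncol(dosages), nrow(map))
  bad <- !(dosages %in% c(0, 1, 2)) & !is.na(dosages)
  if (any(bad)) stopf("dosages must be 0, 1, 2 or NA")
  if (is.null(ril_ids)) ril_ids <- rownames(dosages) %||%
      sprintf("R%04d", seq_len(nrow(dosages)))
  if (anyDuplicated(ril_ids)) stopf("ril ids must be unique")
  dimnames(dosages) <- list(ril_ids, map$marker_id)
  structure(list(dosages = dosages, map = map), class = "genotype_matrix")
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d RILs x %d markers (%d chromosome(s), %.2f%% missing)\n",
              nrow(x$dosages), ncol(x$dosages), length(unique(x$map$chromosome)),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

## one meiotic gamete from a diploid (h1, h2) on one chromosome.
## Crossovers: Poisson process on the cM scale (Haldane, no interference).
meiosis_gamete <- function(h1, h2, pos_cM, length_cM) {
  n_xo <- rpois(1L, length_cM / 100)
  start <- sample.int(2L, 1L) - 1L
  strand <- rep.int(start, length(pos_cM))
  if (n_xo > 0) {
    xo <- sort(runif(n_xo, 0, length_cM))
    strand <- (start + findInterval(pos_cM, xo)) %% 2L
  }
  ifelse(strand == 0L, h1, h2)
}

#' Simulate a biparental BC1S4 RIL population
#'
#' Pedigree: F1 (donor x recurrent) is backcrossed `n_backcross` times to the
#' recurrent parent, then advanced `n_self` generations by single-seed-descent
#' selfing. Gametes are formed by meiosis with crossovers as a Poisson process
#' on the cM scale (Haldane map, no interference). The recurrent parent
#' carries dosage 0 everywhere; output dosage is the donor-allele count.
#'
#' With the default BC1S4 pedigree the expected donor allele frequency is 0.25
#' and the expected residual heterozygosity is 0.5 * (1/2)^4 = 0.03125.
#'
#' @param map a [marker_map()].
#' @param n_ril number of lines to produce.
#' @param n_backcross backcrosses to the recurrent parent after the F1.
#' @param n_self selfing generations after the last backcross.
#' @param seed RNG seed.
#' @return a [genotype_matrix()] with no missing calls.
#' @export
simulate_ril_population <- function(map, n_ril, n_backcross = 1L, n_self = 4L,
                                    seed = 1L) {
  map <- validate_marker_map(as.data.frame(map))
  if (nrow(map) == 0L) stopf("marker map is empty")
  assert_scalar_number(n_ril, "n_ril", lower = 1)
  chroms <- split(seq_len(nrow(map)), map$chromosome)
  pos <- lapply(chroms, function(i) map$position_cM[i])
  len <- vapply(pos, function(p) max(p), numeric(1))  # map length per chrom
  p <- nrow(map)

  gamete_of <- function(ind) {  # ind: list(h1, h2) of full-genome haplotypes
    g <- numeric(p)
    for (k in seq_along(chroms)) {
      i <- chroms[[k]]
      g[i] <- meiosis_gamete(ind$h1[i], ind$h2[i], pos[[k]], len[[k]])
    }
    g
  }

  with_seed(seed, {
    dos <- matrix(0L, n_ril, p)
    f1 <- list(h1 = rep(1, p), h2 = rep(0, p))
    for (r in seq_len(n_ril)) {
      ind <- f1
      for (b in seq_len(n_backcross))
        ind <- list(h1 = gamete_of(ind), h2 = rep(0, p))
      for (s in seq_len(n_self))
        ind <- list(h1 = gamete_of(ind), h2 = gamete_of(ind))
      dos[r, ] <- as.integer(ind$h1 + ind$h2)
    }
    genotype_matrix(dos, map)
  })
}
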