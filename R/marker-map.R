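#' Marker map constructor
#'
#' A marker map is a data frame with one row per SNP giving its identifier,
#' chromosome, physical position (bp) and genetic position (cM). Within each
#' chromosome physical positions must be strictly increasing and genetic
#' positions non-decreasing; marker ids must be unique.
#'
#' @param marker_id character vector of unique marker names.
#' @param chromosome integer chromosome index (>= 1).
#' @param position_bp integer physical position, base pairs.
#' @param position_cM numeric genetic position, centiMorgans.
#' @return a `marker_map` (also a `data.frame`).
#' @export
marker_map <- function(marker_id, chromosome, position_bp, position_cM) {
  m <- data.frame(marker_id = as.character(marker_id),
                  chromosome = as.integer(chromosome),
                  position_bp = as.numeric(position_bp),
                  position_cM = as.numeric(position_cM),
                  stringsAsFactors = FALSE)
  validate_marker_map(m)
}

validate_marker_map <- function(m) {
  if (anyDuplicated(m$marker_id)) stopf("marker ids must be unique")
  if (any(m$chromosome < 1L)) stopf("chromosome indices must be >= 1")
  if (any(m$position_bp < 0) || any(m$position_cM < 0))
    stopf("positions must be non-negative")
  for (ch in unique(m$chromosome)) {
    sub <- m[m$chromosome == ch, ]
    if (is.unsorted(sub$position_bp, strictly = TRUE))
      stopf("position_bp must be strictly increasing within chromosome %d", ch)
    if (is.unsorted(sub$position_cM))
      stopf("position_cM must be non-decreasing within chromosome %d", ch)
  }
  class(m) <- c("marker_map", "data.frame")
  m
}

#' Simulate a marker map
#'
#' Physical positions are drawn uniformly along each chromosome and sorted;
#' genetic positions are proportional to physical positions (uniform
#' recombination rate along the chromosome).
#'
#' @param n_chrom number of chromosomes.
#' @param markers_per_chrom markers on each chromosome (recycled).
#' @param chrom_length_bp chromosome length in bp (recycled).
#' @param chrom_length_cM chromosome length in cM (recycled).
#' @param seed RNG seed.
#' @return a [marker_map()].
#' @export
simulate_marker_map <- function(n_chrom, markers_per_chrom, chrom_length_bp,
                                chrom_length_cM, seed = 1L) {
  assert_scalar_number(n_chrom, "n_chrom", lower = 1)
  if (any(markers_per_chrom <= 0) || any(chrom_length_bp <= 0) ||
      any(chrom_length_cM <= 0))
    stopf("marker counts and chromosome lengths must be positive")
  mpc <- rep_len(as.integer(markers_per_chrom), n_chrom)
  lbp <- rep_len(chrom_length_bp, n_chrom)
  lcm <- rep_len(chrom_length_cM, n_chrom)
  with_seed(seed, {
    pieces <- lapply(seq_len(n_chrom), function(ch) {
      repeat {  # redraw on (vanishingly rare) bp collisions
        bp <- sort(floor(runif(mpc[ch], 0, lbp[ch])))
        if (!anyDuplicated(bp)) break
      }
      data.frame(marker_id = sprintf("c%d_m%03d", ch, seq_len(mpc[ch])),
                 chromosome = ch,
                 position_bp = bp,
                 position_cM = bp / lbp[ch] * lcm[ch],
                 stringsAsFactors = FALSE)
    })
    validate_marker_map(do.call(rbind, pieces))
  })
}
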