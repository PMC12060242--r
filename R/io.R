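#' Genotype / map / phenotype / architecture readers and writers
#'
#' Plain-text interchange: genotypes as CSV (rows = RILs, columns = marker
#' ids, values 0/1/2/NA) with the map as a separate CSV (marker_id,
#' chromosome, position_bp, position_cM); PLINK-style .ped/.map with biallelic
#' A (recurrent) / B (donor) coding and missing = "0 0"; phenotypes as long
#' CSV; architectures as JSON ground truth.
#'
#' @param geno a [genotype_matrix()].
#' @param path,geno_path,map_path,prefix file paths.
#' @name gp_io
NULL

#' @rdname gp_io
#' @export
write_genotype_csv <- function(geno, geno_path, map_path) {
  df <- data.frame(ril_id = rownames(geno$dosages), geno$dosages,
                   check.names = FALSE)
  write.csv(df, geno_path, row.names = FALSE, quote = FALSE)
  write.csv(as.data.frame(geno$map), map_path, row.names = FALSE, quote = FALSE)
  invisible(c(geno_path, map_path))
}

#' @rdname gp_io
#' @export
read_genotype_csv <- function(geno_path, map_path) {
  df <- read.csv(geno_path, check.names = FALSE)
  map <- read.csv(map_path)
  dos <- as.matrix(df[, -1, drop = FALSE])
  rownames(dos) <- df$ril_id
  genotype_matrix(dos, map)
}

#' @rdname gp_io
#' @export
write_plink <- function(geno, prefix) {
  dos <- geno$dosages
  allele <- function(x) {
    out <- c("0 0", "A A", "A B", "B B")[ifelse(is.na(x), 0L, x + 1L) + 1L]
    out
  }
  ped_geno <- apply(dos, 1, function(row) paste(allele(row), collapse = " "))
  ped <- paste(rownames(dos), rownames(dos), 0, 0, 0, -9, ped_geno)
  writeLines(ped, paste0(prefix, ".ped"))
  m <- geno$map
  writeLines(sprintf("%d %s %g %d", m$chromosome, m$marker_id,
                     m$position_cM, m$position_bp),
             paste0(prefix, ".map"))
  invisible(paste0(prefix, c(".ped", ".map")))
}

#' @rdname gp_io
#' @param pheno a [phenotype_table()].
#' @export
write_phenotype_csv <- function(pheno, path) {
  write.csv(as.data.frame(pheno), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname gp_io
#' @export
read_phenotype_csv <- function(path) phenotype_table(read.csv(path))

#' @rdname gp_io
#' @param arch a [trait_architecture()].
#' @export
write_architecture_json <- function(arch, path) {
  jsonlite::write_json(unclass(arch), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname gp_io
#' @export
read_architecture_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  trait_architecture(mu = x$mu,
                     additive_qtl = as.data.frame(x$additive_qtl),
                     epistatic_pairs = as.data.frame(x$epistatic_pairs),
                     env_effects = x$env_effects, target_h2 = x$target_h2)
}
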