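#' Phased genotype container
#'
#' Stores biallelic SNP genotypes with known parental origin as two allele
#' matrices (individuals x SNPs, codes 0/1/`NA`): one for the paternally
#' inherited allele and one for the maternally inherited allele. Allele code 1
#' denotes the counted allele A2 (frequency `p`), 0 the alternative A1.
#' The paternal allele is, by the package-wide convention, the first allele
#' of a phased VCF genotype pair.
#'
#' @param paternal,maternal Integer matrices (individuals x SNPs) with entries
#'   in `{0, 1, NA}`. Missingness must agree between the two matrices.
#' @param sample_ids Character vector of unique individual identifiers.
#' @param snp_ids Character vector of unique SNP identifiers.
#' @param chrom Chromosome per SNP (defaults to `"1"`).
#' @param pos 1-based physical position per SNP (defaults to `seq_len(m)`).
#'
#' @return An object of class `phased_genotypes`.
#' @export
phased_genotypes <- function(paternal, maternal,
                             sample_ids = rownames(paternal),
                             snp_ids = colnames(paternal),
                             chrom = NULL, pos = NULL) {
  paternal <- as.matrix(paternal)
  maternal <- as.matrix(maternal)
  if (!identical(dim(paternal), dim(maternal))) {
    stop("paternal and maternal allele matrices must have the same shape")
  }
  n <- nrow(paternal)
  m <- ncol(paternal)
  if (is.null(sample_ids)) sample_ids <- paste0("ind_", seq_len(n))
  if (is.null(snp_ids)) snp_ids <- paste0("snp_", seq_len(m))
  if (anyDuplicated(sample_ids)) stop("sample ids must be unique")
  if (anyDuplicated(snp_ids)) stop("SNP ids must be unique")
  bad <- function(x) any(!is.na(x) & x != 0L & x != 1L)
  if (bad(paternal) || bad(maternal)) {
    stop("allele codes must be 0, 1 or NA")
  }
  if (!identical(is.na(paternal), is.na(maternal))) {
    stop("missingness must agree between paternal and maternal matrices")
  }
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(pos)) pos <- seq_len(m)
  storage.mode(paternal) <- "integer"
  storage.mode(maternal) <- "integer"
  dimnames(paternal) <- dimnames(maternal) <- list(sample_ids, snp_ids)
  structure(
    list(paternal = paternal, maternal = maternal,
         sample_ids = as.character(sample_ids),
         snp_ids = as.character(snp_ids),
         chrom = as.character(chrom), pos = as.integer(pos)),
    class = "phased_genotypes")
}

#' @export
print.phased_genotypes <- function(x, ...) {
  miss <- mean(is.na(x$paternal))
  cat("<phased_genotypes> ", length(x$sample_ids), " individuals x ",
      length(x$snp_ids), " SNPs (", sprintf("%.2f%%", 100 * miss),
      " missing)\n", sep = "")
  invisible(x)
}

#' @export
dim.phased_genotypes <- function(x) dim(x$paternal)

#' Subset a phased genotype set
#'
#' @param x A [phased_genotypes] object.
#' @param i Individual (row) index.
#' @param j SNP (column) index.
#' @param ... Unused.
#' @return A `phased_genotypes` object.
#' @export
`[.phased_genotypes` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$sample_ids)
  if (missing(j)) j <- seq_along(x$snp_ids)
  phased_genotypes(x$paternal[i, j, drop = FALSE],
                   x$maternal[i, j, drop = FALSE],
                   sample_ids = x$sample_ids[i],
                   snp_ids = x$snp_ids[j],
                   chrom = x$chrom[j], pos = x$pos[j])
}

#' Unphased genotype dosage matrix
#'
#' @param genotypes A [phased_genotypes] object.
#' @return Integer matrix of A2 allele counts (0/1/2, `NA` when missing).
#' @export
genotype_dosage <- function(genotypes) {
  genotypes$paternal + genotypes$maternal
}
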