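#' Read phased genotypes from a VCF file
#'
#' Reads a biallelic, fully phased VCF (GT field with the `|` separator) into
#' a [phased_genotypes] object. The first allele of each genotype pair is
#' taken as the paternally inherited allele, the package-wide convention for
#' parental origin. Unphased or multiallelic records are rejected.
#'
#' @param path Path to a VCF file (plain text or bgzipped).
#' @return A [phased_genotypes] object.
#' @export
read_phased_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) {   # single-record files come back as a vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt) | is.na(alt) | alt == "."
  if (any(multi)) {
    stop("non-biallelic site(s): ",
         paste(utils::head(fix[multi, "ID"], 5), collapse = ", "))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix))
  miss <- is.na(gt) | gt %in% c(".", "./.", ".|.")
  unphased <- !miss & grepl("/", gt, fixed = TRUE)
  if (any(unphased)) {
    idx <- which(unphased, arr.ind = TRUE)[1, ]
    stop("unphased genotype at record ", fix[idx[1], "ID"],
         ", sample ", colnames(gt)[idx[2]],
         ": phased input with '|' separator is required")
  }
  bad <- !miss & !gt %in% c("0|0", "0|1", "1|0", "1|1")
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop("unsupported GT value '", gt[idx[1], idx[2]], "' at record ",
         fix[idx[1], "ID"])
  }
  pat <- ifelse(miss, NA_integer_, as.integer(substr(gt, 1, 1)))
  mat <- ifelse(miss, NA_integer_, as.integer(substr(gt, 3, 3)))
  ids <- fix[, "ID"]
  if (any(is.na(ids) | ids == ".")) {
    ids <- paste0(fix[, "CHROM"], "_", fix[, "POS"])
  }
  phased_genotypes(t(pat), t(mat),
                   sample_ids = colnames(gt), snp_ids = ids,
                   chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]))
}

#' Write phased genotypes to a VCF file
#'
#' Writes a minimal phased VCF v4.2 text file (GT only, `|` separator,
#' paternal allele first). The inverse of [read_phased_vcf()].
#'
#' @param genotypes A [phased_genotypes] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(genotypes, path) {
  g <- genotypes
  n <- length(g$sample_ids)
  gt <- matrix("", nrow = length(g$snp_ids), ncol = n)
  pat <- t(g$paternal)
  mat <- t(g$maternal)
  miss <- is.na(pat)
  gt[] <- paste0(pat, "|", mat)
  gt[miss] <- ".|."
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=imprintgp",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype, paternal allele first\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$sample_ids), collapse = "\t"))
  body <- cbind(g$chrom, g$pos, g$snp_ids, "A", "B", ".", "PASS", ".", "GT", gt)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a phenotype table
#'
#' Reads a tab-separated phenotype file with columns `sample_id`, `y_c`
#' (corrected phenotype), `litter_id`, `birth_year` and `birth_date`
#' (ISO-8601). Rows with a non-numeric corrected phenotype are dropped with a
#' message; duplicate sample ids are an error.
#'
#' @param path Path to a TSV file with a header line.
#' @param genotypes Optional [phased_genotypes]; when given, sample ids are
#'   cross-checked and rows without genotypes are an error.
#' @return A tibble with one row per individual.
#' @export
read_phenotypes <- function(path, genotypes = NULL) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  raw <- read.delim(path, header = TRUE, sep = "\t",
                    colClasses = "character", check.names = FALSE)
  required <- c("sample_id", "y_c", "litter_id", "birth_year", "birth_date")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("phenotype file lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(raw$sample_id)) {
    stop("duplicated sample id(s) in phenotype file: ",
         paste(unique(raw$sample_id[duplicated(raw$sample_id)]), collapse = ", "))
  }
  y <- suppressWarnings(as.numeric(raw$y_c))
  drop <- !is.finite(y)
  if (any(drop)) {
    message(sum(drop), " row(s) with non-numeric y_c dropped")
  }
  out <- tibble::tibble(
    sample_id = raw$sample_id[!drop],
    y_c = y[!drop],
    litter_id = raw$litter_id[!drop],
    birth_year = as.integer(raw$birth_year[!drop]),
    birth_date = as.Date(raw$birth_date[!drop]))
  if (any(is.na(out$birth_date))) stop("unparseable birth_date value(s)")
  if (!is.null(genotypes)) {
    absent <- setdiff(out$sample_id, genotypes$sample_ids)
    if (length(absent)) {
      stop("phenotyped individual(s) without genotypes: ",
           paste(utils::head(absent, 5), collapse = ", "))
    }
  }
  out
}

#' Write a phenotype table
#'
#' @param phenotypes Tibble as returned by [read_phenotypes()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(phenotypes, path) {
  df <- as.data.frame(phenotypes)
  df$birth_date <- format(df$birth_date)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Allele frequencies from phased genotypes
#'
#' The frequency `p_j` of the counted allele A2 at SNP `j`, the mean of the
#' non-missing allele codes over both gametes.
#'
#' @param genotypes A [phased_genotypes] object.
#' @return Named numeric vector of frequencies, one per SNP.
#' @export
allele_frequency <- function(genotypes) {
  calls <- rbind(genotypes$paternal, genotypes$maternal)
  n_called <- colSums(!is.na(calls))
  if (any(n_called == 0)) {
    stop("SNP(s) with no non-missing calls: ",
         paste(genotypes$snp_ids[n_called == 0], collapse = ", "))
  }
  setNames(colMeans(calls, na.rm = TRUE), genotypes$snp_ids)
}

#' Hardy-Weinberg equilibrium test per SNP
#'
#' One-degree-of-freedom chi-square test comparing observed genotype counts
#' (A1A1 / heterozygote / A2A2, reciprocal heterozygotes pooled - the test
#' concerns genotype, not parental origin) with Hardy-Weinberg expectations at
#' the estimated allele frequency. SNPs with a zero expected count (fixed
#' alleles) get p-value 1.
#'
#' @param genotypes A [phased_genotypes] object.
#' @return Tibble with columns `snp_id`, `statistic`, `p_value`.
#' @export
hwe_test <- function(genotypes) {
  g <- genotype_dosage(genotypes)
  n0 <- colSums(g == 0L, na.rm = TRUE)
  n1 <- colSums(g == 1L, na.rm = TRUE)
  n2 <- colSums(g == 2L, na.rm = TRUE)
  n <- n0 + n1 + n2
  if (any(n == 0)) {
    stop("SNP(s) with no non-missing genotypes: ",
         paste(genotypes$snp_ids[n == 0], collapse = ", "))
  }
  p <- (n1 + 2 * n2) / (2 * n)
  e0 <- n * (1 - p)^2
  e1 <- n * 2 * p * (1 - p)
  e2 <- n * p^2
  stat <- numeric(length(n))
  ok <- e0 > 0 & e1 > 0 & e2 > 0
  stat[ok] <- (n0[ok] - e0[ok])^2 / e0[ok] +
    (n1[ok] - e1[ok])^2 / e1[ok] +
    (n2[ok] - e2[ok])^2 / e2[ok]
  pval <- ifelse(ok, pchisq(stat, df = 1, lower.tail = FALSE), 1)
  pval[ok & stat == 0] <- 1
  tibble::tibble(snp_id = genotypes$snp_ids, statistic = unname(stat),
                 p_value = unname(pval))
}

#' Quality-control filter for phased genotypes
#'
#' Applies, in a fixed order: (1) removal of individuals with a call rate
#' below `sample_call_rate_min`; then removal of SNPs with (2) call rate not
#' greater than `snp_call_rate_min`, (3) minor allele frequency not greater
#' than `maf_min` (strict inequality), and (4) Hardy-Weinberg test p-value
#' not greater than `hwe_p_min`.
#'
#' @param genotypes A [phased_genotypes] object.
#' @param maf_min Minimum (exclusive) minor allele frequency. Default 0.01.
#' @param snp_call_rate_min Minimum (exclusive) per-SNP call rate. Default 0.9.
#' @param hwe_p_min Minimum (exclusive) HWE p-value. Default 1e-7.
#' @param sample_call_rate_min Per-sample call rate below which individuals
#'   are excluded. Default 0.8.
#' @return List with elements `genotypes` (the filtered set) and `report`
#'   (a tibble: one row per filter with threshold, units removed/retained).
#' @export
qc_filter <- function(genotypes, maf_min = 0.01, snp_call_rate_min = 0.9,
                      hwe_p_min = 1e-7, sample_call_rate_min = 0.8) {
  stopifnot(maf_min >= 0, maf_min <= 1, snp_call_rate_min >= 0,
            snp_call_rate_min <= 1, sample_call_rate_min >= 0,
            sample_call_rate_min <= 1)
  g <- genotypes
  report <- list()

  sample_cr <- rowMeans(!is.na(g$paternal))
  keep_s <- sample_cr >= sample_call_rate_min
  report$sample_call_rate <- tibble::tibble(
    filter = "sample_call_rate", unit = "sample",
    threshold = sample_call_rate_min,
    n_removed = sum(!keep_s), n_retained = sum(keep_s))
  g <- g[keep_s, ]

  snp_cr <- colMeans(!is.na(g$paternal))
  keep1 <- snp_cr > snp_call_rate_min
  report$snp_call_rate <- tibble::tibble(
    filter = "snp_call_rate", unit = "snp", threshold = snp_call_rate_min,
    n_removed = sum(!keep1), n_retained = sum(keep1))
  g <- g[, keep1]

  p <- allele_frequency(g)
  maf <- pmin(p, 1 - p)
  keep2 <- maf > maf_min
  report$maf <- tibble::tibble(
    filter = "maf", unit = "snp", threshold = maf_min,
    n_removed = sum(!keep2), n_retained = sum(keep2))
  g <- g[, keep2]

  if (length(g$snp_ids)) {
    hwe <- hwe_test(g)
    keep3 <- hwe$p_value > hwe_p_min
  } else {
    keep3 <- logical(0)
  }
  report$hwe <- tibble::tibble(
    filter = "hwe_p", unit = "snp", threshold = hwe_p_min,
    n_removed = sum(!keep3), n_retained = sum(keep3))
  g <- g[, keep3]

  if (length(g$snp_ids) == 0) {
    stop("all SNPs removed by quality control; review the thresholds")
  }
  list(genotypes = g, report = dplyr::bind_rows(report))
}
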