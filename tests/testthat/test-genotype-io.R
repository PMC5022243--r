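# VCF/phenotype IO, allele frequencies, HWE testing and QC filtering.

test_that("phased VCF round-trips the allele matrices exactly", {
  pop <- simulate_population(sim_config(n_individuals = 40, n_snps = 25,
                                        seed = 5))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_phased_vcf(pop$genotypes, path)
  back <- read_phased_vcf(path)
  expect_identical(back$paternal, pop$genotypes$paternal)
  expect_identical(back$maternal, pop$genotypes$maternal)
  expect_identical(back$sample_ids, pop$genotypes$sample_ids)
})

vcf_lines <- function(gt_rows, alt = "B") {
  c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2"), collapse = "\t"),
    vapply(seq_along(gt_rows), function(i) {
      paste(c("1", i, paste0("snp", i), "A", alt, ".", "PASS", ".", "GT",
              gt_rows[[i]]), collapse = "\t")
    }, ""))
}

test_that("GT parsing maps the first allele to the paternal matrix", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf_lines(list(c("0|1", "1|0"), c(".|.", "1|1"))), path)
  g <- read_phased_vcf(path)
  expect_equal(g$paternal["s1", "snp1"], 0L)
  expect_equal(g$maternal["s1", "snp1"], 1L)
  expect_equal(g$paternal["s2", "snp1"], 1L)
  expect_equal(g$maternal["s2", "snp1"], 0L)
  expect_true(is.na(g$paternal["s1", "snp2"]))
  expect_true(is.na(g$maternal["s1", "snp2"]))
})

test_that("unphased and multiallelic records are rejected by name", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf_lines(list(c("0|1", "0/1"))), path)
  expect_error(read_phased_vcf(path), "unphased.*snp1")
  writeLines(vcf_lines(list(c("0|1", "1|1")), alt = "B,C"), path)
  expect_error(read_phased_vcf(path), "non-biallelic")
})

test_that("phenotype reading enforces schema, drops bad y_c, flags duplicates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  hdr <- "sample_id\ty_c\tlitter_id\tbirth_year\tbirth_date"
  writeLines(c(hdr,
               "a\t1.5\tL1\t2010\t2010-02-01",
               "b\tNA\tL1\t2010\t2010-02-01",
               "c\t-0.3\tL2\t2011\t2011-03-05"), path)
  expect_message(ph <- read_phenotypes(path), "1 row")
  expect_equal(nrow(ph), 2)
  expect_equal(ph$sample_id, c("a", "c"))
  expect_s3_class(ph$birth_date, "Date")

  writeLines(c(hdr,
               "a\t1\tL1\t2010\t2010-02-01",
               "a\t2\tL1\t2010\t2010-02-01"), path)
  expect_error(read_phenotypes(path), "duplicated")

  writeLines(c("sample_id\ty_c\tlitter_id\tbirth_year",
               "a\t1\tL1\t2010"), path)
  expect_error(read_phenotypes(path), "birth_date")
})

test_that("phenotype round-trip preserves the table", {
  pop <- small_population()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_phenotypes(pop$phenotypes, path)
  back <- read_phenotypes(path)
  expect_equal(back$y_c, pop$phenotypes$y_c)
  expect_equal(back$birth_date, pop$phenotypes$birth_date)
})

test_that("allele frequency is the mean allele code", {
  expect_equal(unname(allele_frequency(counted_genotypes(0, 0, 0, 4))), 1)
  expect_equal(unname(allele_frequency(three_geno_one_snp())), 0.5)
  set.seed(1)
  n <- 10000
  g <- toy_genotypes(matrix(rbinom(n, 1, 0.4), n, 1),
                     matrix(rbinom(n, 1, 0.4), n, 1))
  expect_equal(unname(allele_frequency(g)), 0.4, tolerance = 0.025)
  g_all_na <- toy_genotypes(matrix(NA_integer_, 2, 1), matrix(NA_integer_, 2, 1))
  expect_error(allele_frequency(g_all_na), "no non-missing")
})

test_that("HWE chi-square matches hand-computed statistics", {
  # exactly at expectation: 25/50/25 at p = 0.5
  g <- counted_genotypes(25, 25, 25, 25)
  hw <- hwe_test(g)
  expect_equal(hw$statistic, 0)
  expect_equal(hw$p_value, 1)
  # no heterozygotes at p = 0.5: chi-square equals n
  g2 <- counted_genotypes(50, 0, 0, 50)
  hw2 <- hwe_test(g2)
  expect_equal(hw2$statistic, 100)
  expect_lt(hw2$p_value, 1e-7)
  # fixed allele: zero expected counts give p = 1
  g3 <- counted_genotypes(0, 0, 0, 10)
  expect_equal(hwe_test(g3)$p_value, 1)
})

test_that("QC applies thresholds strictly and in the documented order", {
  set.seed(2)
  n <- 200
  # SNP1/SNP5 clean p=0.5; SNP2 MAF exactly 0.01; SNP3 HWE-violating
  # (no heterozygotes); SNP4 low call rate (0.875 <= 0.9)
  clean <- function() rbinom(n, 1, 0.5)
  pat <- cbind(clean(), c(rep(1L, 2), rep(0L, n - 2)),
               rep(c(0L, 1L), n / 2), clean(), clean())
  mat <- cbind(clean(), c(rep(1L, 2), rep(0L, n - 2)),
               rep(c(0L, 1L), n / 2), clean(), clean())
  miss <- rep(FALSE, n); miss[1:25] <- TRUE
  pat[miss, 4] <- NA; mat[miss, 4] <- NA
  g <- toy_genotypes(pat, mat)
  res <- qc_filter(g)
  expect_equal(res$genotypes$snp_ids, c("snp_1", "snp_5"))
  rep <- res$report
  expect_equal(rep$n_removed[rep$filter == "sample_call_rate"], 0)
  expect_equal(rep$n_removed[rep$filter == "snp_call_rate"], 1)
  expect_equal(rep$n_removed[rep$filter == "maf"], 1)
  expect_equal(rep$n_removed[rep$filter == "hwe_p"], 1)
  # removed + retained = input at every step
  expect_true(all(rep$n_removed + rep$n_retained == c(n, 5, 4, 3)))

  # sample call rate 0.79 -> removed; 0.80 -> kept
  m <- 100
  pat2 <- matrix(rbinom(3 * m, 1, 0.5), 3, m)
  mat2 <- matrix(rbinom(3 * m, 1, 0.5), 3, m)
  pat2[1, 1:21] <- NA; mat2[1, 1:21] <- NA   # 0.79
  pat2[2, 1:20] <- NA; mat2[2, 1:20] <- NA   # 0.80
  g2 <- toy_genotypes(pat2, mat2)
  res2 <- qc_filter(g2, maf_min = 0, hwe_p_min = 0, snp_call_rate_min = 0)
  expect_equal(nrow(res2$genotypes$paternal), 2)

  # all SNPs removed is an error
  expect_error(qc_filter(g, maf_min = 0.99), "all SNPs removed")
})

test_that("QC is idempotent and leaves clean simulated data untouched", {
  pop <- small_population()
  res1 <- qc_filter(pop$genotypes)
  expect_equal(sum(res1$report$n_removed), 0)
  res2 <- qc_filter(res1$genotypes)
  expect_equal(sum(res2$report$n_removed), 0)
  p <- allele_frequency(res1$genotypes)
  expect_true(all(p > 0.01 & p < 0.99))
})
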