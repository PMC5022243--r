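# Small in-code fixtures shared across test files.

# A phased genotype set built directly from allele matrices.
toy_genotypes <- function(pat, mat, ...) {
  phased_genotypes(as.matrix(pat), as.matrix(mat), ...)
}

# Deterministic three-genotype set at one SNP: A1A1, A1A2 (paternal A1),
# A2A2 -> allele frequency 0.5.
three_geno_one_snp <- function() {
  toy_genotypes(pat = c(0L, 0L, 1L), mat = c(0L, 1L, 1L))
}

# Genotypes with prescribed genotype counts at a single SNP:
# counts = c(n_A1A1, n_A1A2, n_A2A1, n_A2A2), paternal allele listed first.
counted_genotypes <- function(n11, n12, n21, n22) {
  pat <- c(rep(0L, n11), rep(0L, n12), rep(1L, n21), rep(1L, n22))
  mat <- c(rep(0L, n11), rep(1L, n12), rep(0L, n21), rep(1L, n22))
  toy_genotypes(pat, mat)
}

# A small simulated population used by several test files (cached per session).
small_population <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_population(
        sim_config(n_individuals = 500, n_snps = 200, seed = 42))
    }
    cache
  }
})

# Phenotype tibble for litter-only data (no SNPs): y = litter + residual.
litter_only_phenotypes <- function(n_litters, litter_size, s2l, s2e, seed) {
  set.seed(seed)
  n <- n_litters * litter_size
  litter <- rep(seq_len(n_litters), each = litter_size)
  l <- rnorm(n_litters, 0, sqrt(s2l))
  tibble::tibble(
    sample_id = sprintf("id%04d", seq_len(n)),
    y_c = l[litter] + rnorm(n, 0, sqrt(s2e)),
    litter_id = sprintf("L%03d", litter),
    birth_year = 2010L,
    birth_date = as.Date("2010-06-01"))
}

# Empty design matrix set (no SNPs) for litter-only fits.
empty_design <- function(sample_ids) {
  structure(list(freqs = numeric(0), effects = "additive",
                 sample_ids = sample_ids, snp_ids = character(0),
                 M_a = matrix(0, length(sample_ids), 0,
                              dimnames = list(sample_ids, NULL))),
            class = "design_matrix_set")
}
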