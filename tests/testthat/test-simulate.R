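# Synthetic-population generator: allele frequencies, litter-structured phased
# genotypes, mixture-distributed effects, and phenotype assembly.

test_that("allele frequency draws respect the configured range", {
  expect_length(simulate_allele_frequencies(0), 0)
  expect_equal(simulate_allele_frequencies(5, c(0.3, 0.3)), rep(0.3, 5))
  set.seed(3)
  f <- simulate_allele_frequencies(10000, c(0.05, 0.5))
  expect_true(all(f >= 0.05 & f <= 0.5))
  # uniform mean (0.05 + 0.5)/2 = 0.275 by the law of large numbers
  expect_equal(mean(f), 0.275, tolerance = 0.01)
  expect_error(simulate_allele_frequencies(5, c(0, 0.5)), "freq_range")
})

test_that("phased genotypes follow Mendelian litter structure", {
  cfg <- sim_config(n_individuals = 3000, n_snps = 4, seed = 9,
                    mean_litter_size = 3)
  set.seed(cfg$seed)
  # fixed allele and recoverable frequency
  freqs <- c(1 - 1e-12, 0.4, 0.5, 0.2)
  sim <- simulate_phased_genotypes(cfg, freqs)
  g <- sim$genotypes
  expect_equal(nrow(g$paternal), 3000)
  # p ~ 1 gives all A2A2
  expect_true(all(g$paternal[, 1] == 1L & g$maternal[, 1] == 1L))
  # binomial sampling error bound: phat within 0.02 of 0.4 at 2n = 6000
  expect_equal(unname(allele_frequency(g)[2]), 0.4, tolerance = 0.02)
  # full sibs share exactly one litter id; litter sizes >= 1
  expect_equal(length(sim$litter_id), 3000)
  expect_true(all(table(sim$litter_id) >= 1))
  expect_equal(mean(table(sim$litter_id)), 3, tolerance = 0.25)
})

test_that("unit litter size gives one litter per offspring", {
  cfg <- sim_config(n_individuals = 50, n_snps = 2, seed = 1,
                    mean_litter_size = 1)
  set.seed(1)
  sim <- simulate_phased_genotypes(cfg, c(0.5, 0.5))
  expect_equal(length(unique(sim$litter_id)), 50)
})

test_that("SNP effects honour the mixture classes and exact rescaling", {
  set.seed(4)
  pi <- c(0.889, 0.1, 0.01, 0.001)
  n <- 10000
  f <- runif(n, 0.1, 0.9)
  eff <- simulate_snp_effects(n, pi, 1, f, "additive")
  counts <- tabulate(eff$class, nbins = 4)
  # class counts within 3 binomial SDs of n * pi
  expect_true(all(abs(counts - n * pi) <= 3 * sqrt(n * pi * (1 - pi)) + 1))
  # analytic variance hits the target exactly
  expect_equal(sum(2 * f * (1 - f) * eff$effect^2), 1, tolerance = 1e-12)
  # dominance scaling uses the squared weight
  eff_d <- simulate_snp_effects(n, pi, 0.3, f, "dominance")
  expect_equal(sum((2 * f * (1 - f))^2 * eff_d$effect^2), 0.3,
               tolerance = 1e-12)
  # degenerate cases
  expect_true(all(simulate_snp_effects(100, pi, 0, f[1:100], "additive")$effect == 0))
  expect_true(all(simulate_snp_effects(200, c(1, 0, 0, 0), 1, f[1:200],
                                       "imprinting")$class == 1L))
})

test_that("stored genetic values equal design-matrix products exactly", {
  pop <- small_population()
  des <- design_matrices(pop$genotypes, freqs = pop$freqs)
  expect_identical(unname(drop(des$M_a %*% pop$true_effects$q_a)),
                   pop$true_values$additive)
  expect_identical(unname(drop(des$M_d %*% pop$true_effects$q_d)),
                   pop$true_values$dominance)
  expect_identical(unname(drop(des$M_i %*% pop$true_effects$q_i)),
                   pop$true_values$imprinting)
  # phenotype assembly: y_c minus all stored parts is the birth-year effect,
  # constant within year
  resid <- pop$phenotypes$y_c - rowSums(pop$true_values[, -1])
  expect_true(all(tapply(resid, pop$phenotypes$birth_year, sd) < 1e-12))
})

test_that("degenerate variance targets give deterministic phenotypes", {
  tv0 <- c(additive = 0, dominance = 0, imprinting = 0, litter = 0,
           residual = 0)
  cfg <- sim_config(n_individuals = 60, n_snps = 10, seed = 2,
                    target_variances = tv0, n_birth_years = 1,
                    birth_year_effect_sd = 0)
  pop <- simulate_population(cfg)
  expect_lt(var(pop$phenotypes$y_c), 1e-24)

  tv <- tv0; tv["additive"] <- 0.5
  cfg2 <- sim_config(n_individuals = 60, n_snps = 10, seed = 2,
                     target_variances = tv, n_birth_years = 1,
                     birth_year_effect_sd = 0)
  pop2 <- simulate_population(cfg2)
  expect_equal(pop2$phenotypes$y_c, pop2$true_values$additive)
})

test_that("realized variances match targets at moderate size", {
  cfg <- sim_config(n_individuals = 4000, n_snps = 400, seed = 8)
  pop <- simulate_population(cfg)
  tv <- cfg$target_variances
  # genetic components rescaled: realized within 15% of target
  for (comp in c("additive", "dominance", "imprinting")) {
    expect_equal(unname(pop$realized_variances[comp]), unname(tv[comp]),
                 tolerance = 0.15)
  }
  # phenotypic variance near the component total (backfat-like ~ 1.117)
  expect_equal(unname(pop$realized_variances["phenotypic"]),
               sum(tv) + cfg$birth_year_effect_sd^2, tolerance = 0.1)
})

test_that("reciprocal heterozygotes are balanced", {
  pop <- small_population()
  Mi <- imprinting_codes(pop$genotypes)
  n_pos <- sum(Mi == 1)
  n_neg <- sum(Mi == -1)
  expect_equal(n_pos / (n_pos + n_neg), 0.5,
               tolerance = 3 / sqrt(n_pos + n_neg))
})

test_that("simulation is reproducible and writes readable fixtures", {
  cfg <- sim_config(n_individuals = 40, n_snps = 15, seed = 77)
  p1 <- simulate_population(cfg)
  p2 <- simulate_population(cfg)
  expect_identical(p1$phenotypes$y_c, p2$phenotypes$y_c)
  expect_identical(p1$genotypes$paternal, p2$genotypes$paternal)

  dir <- withr::local_tempdir()
  files <- write_population(p1, file.path(dir, "pop"))
  g <- read_phased_vcf(files[["vcf"]])
  expect_identical(g$paternal, p1$genotypes$paternal)
  ph <- read_phenotypes(files[["pheno"]], g)
  expect_equal(ph$y_c, p1$phenotypes$y_c)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(mixing_proportions = c(0.5, 0.5, 0.1, 0.1)),
               "summing to 1")
  expect_error(sim_config(allele_freq_range = c(0.001, 0.5)), "0.01")
  tv <- c(additive = -1, dominance = 0, imprinting = 0, litter = 0,
          residual = 1)
  expect_error(sim_config(target_variances = tv), ">= 0")
})
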