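# Gibbs sampler: initialization, full-conditional correctness against closed
# forms, variance-component oracles, chain summaries and predictions.

make_chain_data <- function(pop, effects = c("additive", "dominance",
                                             "imprinting")) {
  des <- design_matrices(pop$genotypes, freqs = pop$freqs, effects = effects)
  imprintgp:::prepare_model_data(pop$phenotypes, des, effects)
}

test_that("chain initialization satisfies its contracts", {
  pop <- small_population()
  spec <- model_spec("ADI", chain_length = 100, burn_in = 10, thinning = 1)
  data <- make_chain_data(pop)
  st <- initialize_chain(spec, data)
  for (cv in st$class_var) expect_true(all(diff(cv) > 0))
  expect_true(st$sigma2_e > 0 && st$sigma2_l > 0)
  expect_equal(st$q[[1]], rep(0, 200))
  # year means
  expect_equal(st$b, as.numeric(tapply(data$y, data$year, mean)))
  # determinism of the full fit
  st2 <- initialize_chain(spec, data)
  expect_identical(st, st2)

  # constant phenotype: positive floored residual variance
  dc <- data
  dc$y <- rep(1, length(dc$y))
  stc <- initialize_chain(spec, dc)
  expect_gt(stc$sigma2_e, 0)

  # too few observations for the year structure
  tiny <- lapply(data, function(x) x)
  tiny$y <- data$y[1:3]
  tiny$year <- factor(rep(2000:2002, 1))
  expect_error(initialize_chain(spec, tiny), "at least")
})

test_that("single-SNP effect draws match the closed-form conditional", {
  set.seed(30)
  n <- 80
  pat <- matrix(rbinom(n, 1, 0.4), n, 1)
  mat <- matrix(rbinom(n, 1, 0.4), n, 1)
  g <- phased_genotypes(pat, mat)
  p <- allele_frequency(g)
  des <- design_matrices(g, freqs = p, effects = "additive")
  ph <- tibble::tibble(sample_id = g$sample_ids,
                       y_c = rnorm(n, 0.3 * des$M_a[, 1], 0.6),
                       litter_id = sprintf("L%02d", rep(1:20, each = 4)),
                       birth_year = 2005L,
                       birth_date = as.Date("2005-06-01"))
  s2e <- 0.36; s2q <- 0.25
  spec <- model_spec("additive", mixing_proportions = c(1, 0, 0, 0),
                     chain_length = 10, burn_in = 5, thinning = 1,
                     fixed = list(
                       class_variances = list(additive = s2q * c(1, 2, 3, 4)),
                       sigma2_e = s2e, sigma2_l = 1e-8))
  data <- imprintgp:::prepare_model_data(ph, des, "additive")
  st <- initialize_chain(spec, data)
  st$l <- rep(0, nlevels(data$litter))

  # with b and l held fixed the draw of q is iid from its full conditional
  m1 <- des$M_a[, 1]
  C <- sum(m1^2)
  resid0 <- data$y - st$b[1]
  rhs <- sum(m1 * resid0)
  post_mean <- rhs / (C + s2e / s2q)
  post_sd <- sqrt(s2e / (C + s2e / s2q))

  set.seed(31)
  draws <- replicate(1500, {
    st <<- imprintgp:::gibbs_iteration(st, data, spec,
                                       update = list(b = FALSE, l = FALSE))
    st$q[[1]][1]
  })
  expect_equal(mean(draws), post_mean, tolerance = 4 * post_sd / sqrt(1500) /
                 max(abs(post_mean), 1e-12))
  expect_equal(sd(draws), post_sd, tolerance = 0.1)
})

test_that("with no SNPs the chain matches the one-way ANOVA oracle", {
  n_lit <- 200; size <- 5
  ph <- litter_only_phenotypes(n_lit, size, s2l = 1, s2e = 2, seed = 32)
  des <- empty_design(ph$sample_id)
  spec <- model_spec("additive", chain_length = 3000, burn_in = 500,
                     thinning = 2, seed = 33)
  fit <- fit_genomic_mixture(ph, des, spec)

  # method-of-moments oracle from the one-way ANOVA decomposition
  av <- anova(lm(y_c ~ litter_id, data = ph))
  msb <- av$`Mean Sq`[1]; msw <- av$`Mean Sq`[2]
  s2e_hat <- msw
  s2l_hat <- (msb - msw) / size

  expect_equal(mean(fit$samples[, "sigma2_e"]), s2e_hat, tolerance = 0.05)
  expect_equal(mean(fit$samples[, "sigma2_l"]), s2l_hat, tolerance = 0.15)
})

test_that("saved-sample bookkeeping, ordering and resynchronization hold", {
  pop <- small_population()
  des <- design_matrices(pop$genotypes, freqs = pop$freqs)
  # chain_length = burn_in + thinning saves exactly one sample
  spec1 <- model_spec("AD", chain_length = 60, burn_in = 50, thinning = 10,
                      seed = 2)
  fit1 <- fit_genomic_mixture(pop$phenotypes, des, spec1)
  expect_equal(fit1$n_saved, 1L)

  spec <- model_spec("ADI", chain_length = 1500, burn_in = 300, thinning = 3,
                     seed = 5)
  fit <- fit_genomic_mixture(pop$phenotypes, des, spec)
  expect_equal(fit$n_saved, 400L)
  # ordering constraint in every saved sample, per effect type
  for (e in c("additive", "dominance", "imprinting")) {
    cv <- fit$samples[, paste0("v_", e, "_", 1:4)]
    expect_true(all(cv[, 1] < cv[, 2] & cv[, 2] < cv[, 3] & cv[, 3] < cv[, 4]))
    expect_true(all(cv > 0))
  }
  # incremental residuals stay synchronized with recomputed residuals
  expect_lt(fit$max_resync_diff, 1e-6)
  # identical seed and data reproduce the summary exactly
  fit2 <- fit_genomic_mixture(pop$phenotypes, des, spec)
  expect_identical(fit$samples, fit2$samples)
  expect_identical(fit$snp_effects, fit2$snp_effects)
  expect_identical(fit$lpml, fit2$lpml)
})

test_that("time-series SE behaves like a batch-means estimator", {
  expect_error(mcmc_standard_error(1:5), "at least 10")
  const <- mcmc_standard_error(rep(3, 100))
  expect_equal(const$se, 0)
  expect_true(const$converged)

  set.seed(34)
  iid <- mcmc_standard_error(rnorm(10000))
  expect_equal(iid$se, 0.01, tolerance = 0.35)
  expect_equal(iid$basis, "posterior_sd")

  # AR(1) with phi = 0.99: variance inflation ~ (1+phi)/(1-phi) ~ 199,
  # so the SE must be far above the iid value
  ar <- as.numeric(arima.sim(list(ar = 0.99), 10000))
  ar_se <- mcmc_standard_error(ar)$se
  expect_gt(ar_se, 5 * iid$se)
})

test_that("genetic-value predictions follow the model scope", {
  pop <- small_population()
  des <- design_matrices(pop$genotypes, freqs = pop$freqs)
  # a fit object with the true effects plugged in predicts the true values
  fake <- structure(list(
    effects = c("additive", "dominance", "imprinting"),
    snp_effects = tibble::tibble(
      snp_id = pop$genotypes$snp_ids,
      q_additive = pop$true_effects$q_a,
      q_dominance = pop$true_effects$q_d,
      q_imprinting = pop$true_effects$q_i)), class = "genomic_fit")
  gtv <- predict_genetic_values(fake, des, "GTV")
  expect_equal(gtv$value,
               pop$true_values$additive + pop$true_values$dominance +
                 pop$true_values$imprinting)
  gbv <- predict_genetic_values(fake, des, "GBV")
  expect_equal(gbv$value, pop$true_values$additive)

  # additive-only model: GBV and GTV coincide
  fake_a <- fake
  fake_a$effects <- "additive"
  expect_equal(predict_genetic_values(fake_a, des, "GTV")$value, gbv$value)

  # zero effects predict zero
  fake0 <- fake
  fake0$snp_effects$q_additive <- 0
  fake0$snp_effects$q_dominance <- 0
  fake0$snp_effects$q_imprinting <- 0
  expect_true(all(predict_genetic_values(fake0, des, "GTV")$value == 0))

  # requesting an effect the design lacks is an error
  des_a <- design_matrices(pop$genotypes, freqs = pop$freqs,
                           effects = "additive")
  expect_error(predict_genetic_values(fake, des_a, "GTV"), "lacks")
})

test_that("permuting SNP order leaves posterior summaries unchanged up to MCMC error", {
  pop <- simulate_population(sim_config(n_individuals = 400, n_snps = 150,
                                        seed = 15))
  des <- design_matrices(pop$genotypes, freqs = pop$freqs)
  spec <- model_spec("AD", chain_length = 2500, burn_in = 800, thinning = 3,
                     seed = 4)
  fit <- fit_genomic_mixture(pop$phenotypes, des, spec)

  perm <- sample(seq_along(pop$genotypes$snp_ids))
  g2 <- pop$genotypes[, perm]
  des2 <- design_matrices(g2, freqs = pop$freqs[perm])
  fit2 <- fit_genomic_mixture(pop$phenotypes, des2, spec)

  h2 <- function(f) attr(variance_decomposition(f), "narrow_h2")
  expect_equal(h2(fit), h2(fit2), tolerance = 0.35)
  expect_equal(mean(fit$samples[, "sigma2_e"]),
               mean(fit2$samples[, "sigma2_e"]), tolerance = 0.1)
})
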