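#' Configuration for a synthetic phased population
#'
#' Defines the study conditions a simulated population emulates: full-sib
#' litters nested in founder matings, biallelic SNPs in linkage equilibrium,
#' and corrected phenotypes built from birth-year effects, additive, dominance
#' and imprinting SNP effects (four-component normal-mixture architecture),
#' litter effects and residuals. Defaults mirror a Duroc backfat-thickness
#' analysis: 8113 individuals, 33004 SNPs, mean full-sib family size 2.44,
#' variance targets (in squared phenotype units, mm^2)
#' `additive = 0.341`, `dominance = 0.045`, `imprinting = 0.015`,
#' `litter = 0.059`, `residual = 0.657`, mixing proportions
#' `(0.889, 0.1, 0.01, 0.001)`, birth years spanning 17 years and a hold-out
#' fraction of 0.23 (the most recently born individuals).
#'
#' @param n_individuals Number of offspring (phenotyped, genotyped).
#' @param n_snps Number of biallelic SNPs.
#' @param allele_freq_range Range (low, high) for uniform allele frequencies
#'   of the counted allele; `low` must be at least the 0.01 MAF floor.
#' @param target_variances Named numeric vector with entries `additive`,
#'   `dominance`, `imprinting`, `litter`, `residual` (all >= 0). Genetic
#'   components are hit exactly by rescaling the simulated effect vectors.
#' @param mixing_proportions Four mixture proportions summing to 1.
#' @param mean_litter_size Mean full-sib litter size; sizes are drawn as
#'   1 + Poisson(`mean_litter_size` - 1), so every litter has at least one
#'   offspring.
#' @param n_birth_years Number of calendar years the birth dates span.
#' @param birth_year_effect_sd SD of the fixed birth-year effects
#'   (phenotype units).
#' @param validation_fraction Fraction of individuals (the latest-born) that
#'   fall on/after the train/validation cutoff date.
#' @param seed Integer seed; together with the configuration it fully
#'   determines the simulated population.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_individuals = 8113,
                       n_snps = 33004,
                       allele_freq_range = c(0.05, 0.95),
                       target_variances = c(additive = 0.341,
                                            dominance = 0.045,
                                            imprinting = 0.015,
                                            litter = 0.059,
                                            residual = 0.657),
                       mixing_proportions = c(0.889, 0.1, 0.01, 0.001),
                       mean_litter_size = 2.44,
                       n_birth_years = 17,
                       birth_year_effect_sd = 0.25,
                       validation_fraction = 0.23,
                       seed = 1L) {
  stopifnot(n_individuals >= 0, n_snps >= 0, mean_litter_size >= 1,
            n_birth_years >= 1, birth_year_effect_sd >= 0,
            validation_fraction > 0, validation_fraction < 1)
  if (length(mixing_proportions) != 4 || any(mixing_proportions < 0) ||
      abs(sum(mixing_proportions) - 1) > 1e-12) {
    stop("mixing_proportions must be 4 non-negative values summing to 1")
  }
  needed <- c("additive", "dominance", "imprinting", "litter", "residual")
  if (!all(needed %in% names(target_variances))) {
    stop("target_variances must name: ", paste(needed, collapse = ", "))
  }
  if (any(target_variances < 0)) stop("target variances must be >= 0")
  if (length(allele_freq_range) != 2 ||
      allele_freq_range[1] > allele_freq_range[2] ||
      allele_freq_range[1] < 0.01 || allele_freq_range[2] >= 1 ||
      allele_freq_range[1] <= 0) {
    stop("allele_freq_range must satisfy 0.01 <= low <= high < 1")
  }
  structure(list(
    n_individuals = as.integer(n_individuals),
    n_snps = as.integer(n_snps),
    allele_freq_range = as.numeric(allele_freq_range),
    target_variances = target_variances[needed],
    mixing_proportions = as.numeric(mixing_proportions),
    mean_litter_size = mean_litter_size,
    n_birth_years = as.integer(n_birth_years),
    birth_year_effect_sd = birth_year_effect_sd,
    validation_fraction = validation_fraction,
    seed = as.integer(seed)), class = "sim_config")
}

#' Draw SNP allele frequencies
#'
#' Uniform draws on `[low, high]` for the counted-allele frequency, so the
#' minor allele frequency never falls below `low` (or `1 - high`).
#'
#' @param n_snps Number of SNPs.
#' @param freq_range Numeric pair `(low, high)` with `0 < low <= high < 1`.
#' @return Numeric vector of length `n_snps`.
#' @export
simulate_allele_frequencies <- function(n_snps, freq_range = c(0.05, 0.95)) {
  if (length(freq_range) != 2 || freq_range[1] <= 0 || freq_range[2] >= 1 ||
      freq_range[1] > freq_range[2]) {
    stop("freq_range must satisfy 0 < low <= high < 1")
  }
  runif(n_snps, freq_range[1], freq_range[2])
}

#' Simulate phased genotypes with full-sib litter structure
#'
#' Two generations: each litter gets its own founder sire and dam whose
#' gametes are independent Bernoulli(`p_j`) draws per SNP (linkage
#' equilibrium); every offspring receives one gamete from each parent by
#' Mendelian sampling. The paternal allele is recorded as the first allele of
#' the phase pair. Full sibs share exactly one litter.
#'
#' @param config A [sim_config].
#' @param freqs Allele frequencies per SNP (length `config$n_snps`).
#' @return List with `genotypes` (a [phased_genotypes] of the offspring) and
#'   `litter_id` (character vector, one entry per offspring).
#' @export
simulate_phased_genotypes <- function(config, freqs) {
  n <- config$n_individuals
  m <- config$n_snps
  stopifnot(length(freqs) == m)
  if (n == 0) {
    return(list(genotypes = phased_genotypes(
      matrix(integer(0), 0, m), matrix(integer(0), 0, m),
      sample_ids = character(0)), litter_id = character(0)))
  }
  sizes <- 1L + rpois(n, max(config$mean_litter_size - 1, 0))
  cum <- cumsum(sizes)
  k <- which(cum >= n)[1]
  sizes <- sizes[seq_len(k)]
  sizes[k] <- sizes[k] - (cum[k] - n)
  litter <- rep(seq_len(k), sizes)

  draw_gamete <- function() {
    matrix(rbinom(k * m, 1L, rep(freqs, each = k)), nrow = k, ncol = m)
  }
  sire_pat <- draw_gamete(); sire_mat <- draw_gamete()
  dam_pat <- draw_gamete(); dam_mat <- draw_gamete()

  pick <- function(first, second) {
    u <- matrix(runif(n * m) < 0.5, n, m)
    ifelse(u, first[litter, , drop = FALSE], second[litter, , drop = FALSE])
  }
  pat <- pick(sire_pat, sire_mat)   # gamete transmitted by the sire
  mat <- pick(dam_pat, dam_mat)     # gamete transmitted by the dam

  geno <- phased_genotypes(pat, mat,
                           sample_ids = sprintf("ind_%05d", seq_len(n)),
                           snp_ids = sprintf("snp_%05d", seq_len(m)))
  list(genotypes = geno, litter_id = sprintf("lit_%05d", litter))
}

#' Simulate SNP effects from a four-component normal mixture
#'
#' Each SNP is assigned a mixture class with probabilities
#' `mixing_proportions` and its effect drawn from the class normal (relative
#' class variances 0.1, 1, 10, 100). The whole vector is then rescaled so the
#' analytic genetic variance, `sum_j w_j q_j^2` with per-SNP weight
#' `w_j = 2 p_j (1 - p_j)` for additive and imprinting effects and
#' `w_j = (2 p_j (1 - p_j))^2` for dominance effects, equals
#' `target_variance` exactly. A zero target gives a zero vector.
#'
#' @param n_snps Number of SNPs.
#' @param mixing_proportions Four mixture proportions summing to 1.
#' @param target_variance Genetic variance the effect vector must explain.
#' @param freqs Allele frequencies per SNP.
#' @param effect_type One of `"additive"`, `"dominance"`, `"imprinting"`.
#' @return Tibble with columns `effect` and `class` (1-4).
#' @export
simulate_snp_effects <- function(n_snps, mixing_proportions, target_variance,
                                 freqs, effect_type = c("additive",
                                                        "dominance",
                                                        "imprinting")) {
  effect_type <- match.arg(effect_type)
  stopifnot(target_variance >= 0, length(freqs) == n_snps)
  cls <- sample.int(4L, n_snps, replace = TRUE, prob = mixing_proportions)
  if (n_snps == 0) return(tibble::tibble(effect = numeric(0), class = integer(0)))
  ladder <- c(0.1, 1, 10, 100)
  q <- rnorm(n_snps, 0, sqrt(ladder[cls]))
  w <- 2 * freqs * (1 - freqs)
  if (effect_type == "dominance") w <- w^2
  if (target_variance == 0) {
    q <- rep(0, n_snps)
  } else {
    avar <- sum(w * q^2)
    if (avar <= 0) stop("degenerate effect draw; cannot rescale")
    q <- q * sqrt(target_variance / avar)
  }
  tibble::tibble(effect = q, class = as.integer(cls))
}

#' Simulate corrected phenotypes
#'
#' Builds `y_c` = birth-year effect + `M_a q_a + M_d q_d + M_i q_i` + litter
#' effect + residual, with litter effects drawn once per litter and i.i.d.
#' residuals. Littermates share a birth date; dates are laid out over the
#' configured span of years so that the last `validation_fraction` of
#' individuals falls on/after the train/validation cutoff date (stored as
#' attribute `cutoff_date`).
#'
#' @param sim List with `genotypes`, `litter_id` and per-effect true-effect
#'   vectors `q_a`, `q_d`, `q_i` (as from [simulate_snp_effects()]).
#' @param config A [sim_config].
#' @param freqs Allele frequencies used to centre the design matrices (the
#'   observed frequencies of the simulated population).
#' @return List with `phenotypes` (tibble: `sample_id`, `y_c`, `litter_id`,
#'   `birth_year`, `birth_date`), `true_values` (tibble of per-individual
#'   genetic/litter values) and `cutoff_date`.
#' @export
simulate_phenotypes <- function(sim, config, freqs) {
  geno <- sim$genotypes
  n <- length(geno$sample_ids)
  des <- design_matrices(geno, freqs = freqs)
  g_a <- unname(drop(des$M_a %*% sim$q_a))
  g_d <- unname(drop(des$M_d %*% sim$q_d))
  g_i <- unname(drop(des$M_i %*% sim$q_i))

  litter <- sim$litter_id
  litters <- unique(litter)
  n_lit <- length(litters)

  # birth dates: litters evenly spaced over the year span, littermates share
  start <- as.Date("2000-01-01")
  span_days <- config$n_birth_years * 365L
  lit_day <- floor((seq_len(n_lit) - 0.5) / n_lit * (span_days - 1))
  lit_date <- start + lit_day
  birth_date <- lit_date[match(litter, litters)]
  birth_year <- as.integer(format(birth_date, "%Y"))

  # cutoff at the first litter boundary past the target training size, so a
  # litter is never split across training and validation
  n_train <- max(1L, min(n - 1L, round((1 - config$validation_fraction) * n)))
  boundary <- which(seq_len(n) > n_train &
                      litter != dplyr::lag(litter, default = ""))
  idx <- if (length(boundary)) boundary[1] else min(n_train + 1L, n)
  cutoff_date <- birth_date[idx]

  years <- sort(unique(birth_year))
  year_eff <- setNames(rnorm(length(years), 0, config$birth_year_effect_sd),
                       years)
  lit_eff <- setNames(rnorm(n_lit, 0,
                            sqrt(config$target_variances[["litter"]])),
                      litters)
  resid <- rnorm(n, 0, sqrt(config$target_variances[["residual"]]))

  y <- year_eff[as.character(birth_year)] + g_a + g_d + g_i +
    lit_eff[litter] + resid

  list(
    phenotypes = tibble::tibble(
      sample_id = geno$sample_ids,
      y_c = unname(y),
      litter_id = litter,
      birth_year = birth_year,
      birth_date = birth_date),
    true_values = tibble::tibble(
      sample_id = geno$sample_ids,
      additive = g_a, dominance = g_d, imprinting = g_i,
      litter_value = unname(lit_eff[litter]), residual = resid),
    cutoff_date = cutoff_date)
}

#' Simulate a phased population with known genetic architecture
#'
#' End-to-end generator: allele frequencies, phased litter-structured
#' genotypes, mixture-distributed additive/dominance/imprinting SNP effects
#' (rescaled to hit the target variances exactly), and corrected phenotypes.
#' The configuration plus seed fully determine the output.
#'
#' @param config A [sim_config].
#' @return An object of class `sim_population`: a list with `genotypes`,
#'   `phenotypes`, `true_effects` (per-SNP classes and effects),
#'   `true_values` (per-individual component values), `realized_variances`,
#'   `freqs` (observed allele frequencies used for centring and scaling),
#'   `cutoff_date` and the `config`.
#' @export
simulate_population <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tv <- config$target_variances
  base_freqs <- simulate_allele_frequencies(config$n_snps,
                                            config$allele_freq_range)
  gsim <- simulate_phased_genotypes(config, base_freqs)
  freqs <- allele_frequency(gsim$genotypes)  # observed, used throughout
  eff <- lapply(
    setNames(c("additive", "dominance", "imprinting"),
             c("q_a", "q_d", "q_i")),
    function(ty) simulate_snp_effects(config$n_snps,
                                      config$mixing_proportions,
                                      tv[[ty]], freqs, effect_type = ty))
  sim <- list(genotypes = gsim$genotypes, litter_id = gsim$litter_id,
              q_a = eff$q_a$effect, q_d = eff$q_d$effect,
              q_i = eff$q_i$effect)
  ph <- simulate_phenotypes(sim, config, freqs)

  realized <- c(additive = var(ph$true_values$additive),
                dominance = var(ph$true_values$dominance),
                imprinting = var(ph$true_values$imprinting),
                litter = var(ph$true_values$litter_value),
                residual = var(ph$true_values$residual),
                phenotypic = var(ph$phenotypes$y_c))

  structure(list(
    genotypes = gsim$genotypes,
    phenotypes = ph$phenotypes,
    true_effects = tibble::tibble(
      snp_id = gsim$genotypes$snp_ids,
      q_a = eff$q_a$effect, class_a = eff$q_a$class,
      q_d = eff$q_d$effect, class_d = eff$q_d$class,
      q_i = eff$q_i$effect, class_i = eff$q_i$class),
    true_values = ph$true_values,
    realized_variances = realized,
    freqs = freqs,
    cutoff_date = ph$cutoff_date,
    config = config), class = "sim_population")
}

#' @export
print.sim_population <- function(x, ...) {
  cat("<sim_population> ", nrow(x$phenotypes), " individuals, ",
      length(x$genotypes$snp_ids), " SNPs, ",
      length(unique(x$phenotypes$litter_id)), " litters\n", sep = "")
  cat("  realized variances: ",
      paste(names(x$realized_variances),
            signif(x$realized_variances, 3), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Write a simulated population to disk
#'
#' Emits the phased VCF, the phenotype TSV and two ground-truth TSVs (per-SNP
#' effects/classes; per-individual component values) under a common prefix.
#'
#' @param population A [simulate_population()] result.
#' @param out_prefix Path prefix (directory must exist).
#' @return Named character vector of the files written, invisibly.
#' @export
write_population <- function(population, out_prefix) {
  files <- c(
    vcf = paste0(out_prefix, "_genotypes.vcf"),
    pheno = paste0(out_prefix, "_phenotypes.tsv"),
    effects = paste0(out_prefix, "_true_effects.tsv"),
    values = paste0(out_prefix, "_true_values.tsv"))
  write_phased_vcf(population$genotypes, files[["vcf"]])
  write_phenotypes(population$phenotypes, files[["pheno"]])
  write.table(as.data.frame(population$true_effects), files[["effects"]],
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(population$true_values), files[["values"]],
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(files)
}
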