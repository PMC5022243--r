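#' Specify a Bayesian mixture model
#'
#' Configuration for the Gibbs sampler: which genetic effects enter the model
#' (the model names A, AD, AI and ADI are shorthands for the effect sets), the
#' known mixing proportions of the four-component normal mixture prior on SNP
#' effects, and the chain control. The additive effect is always included.
#'
#' @param effects Either a model shorthand (`"A"`, `"AD"`, `"AI"`, `"ADI"`) or
#'   a character vector containing `"additive"` and optionally `"dominance"`
#'   and/or `"imprinting"`.
#' @param mixing_proportions Four mixture proportions summing to 1; default
#'   `c(0.889, 0.1, 0.01, 0.001)`.
#' @param chain_length Total Gibbs iterations (default 50000).
#' @param burn_in Iterations discarded before saving (default 20000).
#' @param thinning Keep every `thinning`-th post-burn-in sample (default 10).
#' @param seed Integer seed for the chain.
#' @param fixed Optional list for degenerate/diagnostic runs: any of
#'   `class_variances` (named list per effect, 4 increasing values each, held
#'   fixed), `sigma2_e`, `sigma2_l`. Parameters named here are not updated.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(effects = "A",
                       mixing_proportions = c(0.889, 0.1, 0.01, 0.001),
                       chain_length = 50000, burn_in = 20000, thinning = 10,
                       seed = 1L, fixed = NULL) {
  shorthand <- c(A = "additive",
                 AD = "additive,dominance",
                 AI = "additive,imprinting",
                 ADI = "additive,dominance,imprinting")
  if (length(effects) == 1 && effects %in% names(shorthand)) {
    model_name <- effects
    effects <- strsplit(shorthand[[effects]], ",")[[1]]
  } else {
    effects <- match.arg(effects, c("additive", "dominance", "imprinting"),
                         several.ok = TRUE)
    model_name <- paste0(c("A", "D", "I")[
      c("additive", "dominance", "imprinting") %in% effects], collapse = "")
  }
  if (!"additive" %in% effects) stop("the additive effect is always included")
  if (length(mixing_proportions) != 4 || any(mixing_proportions < 0) ||
      abs(sum(mixing_proportions) - 1) > 1e-12) {
    stop("mixing_proportions must be 4 non-negative values summing to 1")
  }
  chain_length <- as.integer(chain_length)
  burn_in <- as.integer(burn_in)
  thinning <- as.integer(thinning)
  if (burn_in >= chain_length) stop("burn_in must be smaller than chain_length")
  if (thinning < 1 || (chain_length - burn_in) < thinning) {
    stop("chain must save at least one post-burn-in sample")
  }
  structure(list(effects = effects, model_name = model_name,
                 mixing_proportions = as.numeric(mixing_proportions),
                 chain_length = chain_length, burn_in = burn_in,
                 thinning = thinning, seed = as.integer(seed),
                 fixed = fixed), class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> model ", x$model_name, " (",
      paste(x$effects, collapse = " + "), ")\n", sep = "")
  cat("  pi = (", paste(x$mixing_proportions, collapse = ", "),
      "); chain ", x$chain_length, ", burn-in ", x$burn_in,
      ", thinning ", x$thinning, ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# Align phenotypes with design matrices and encode factors for the sampler.
prepare_model_data <- function(phenotypes, design, effects) {
  stopifnot(inherits(design, "design_matrix_set"))
  need <- c(additive = "M_a", dominance = "M_d", imprinting = "M_i")[effects]
  absent <- need[!need %in% names(design)]
  if (length(absent)) {
    stop("design matrices missing for effect(s): ",
         paste(names(absent), collapse = ", "))
  }
  idx <- match(phenotypes$sample_id, design$sample_ids)
  if (any(is.na(idx))) {
    stop("phenotyped individual(s) without design rows: ",
         paste(utils::head(phenotypes$sample_id[is.na(idx)], 5), collapse = ", "))
  }
  year <- factor(phenotypes$birth_year)
  litter <- factor(phenotypes$litter_id)
  list(y = as.numeric(phenotypes$y_c),
       year = year, litter = litter,
       M = lapply(unname(need), function(nm) design[[nm]][idx, , drop = FALSE]),
       effects = effects,
       sample_ids = phenotypes$sample_id,
       snp_ids = design$snp_ids,
       freqs = design$freqs)
}

#' Initialize the Gibbs chain
#'
#' Birth-year effects start at the within-year phenotype means, litter and
#' SNP effects at zero, the residual variance at half the phenotypic variance
#' and the litter variance at 5 % of it (both floored), and the mixture class
#' variances on a geometric ladder that satisfies the ordering constraint
#' `sigma2_pi1 < sigma2_pi2 < sigma2_pi3 < sigma2_pi4`.
#'
#' @param spec A [model_spec].
#' @param data Internal model data as built by `prepare_model_data()`, or a
#'   list with elements `y`, `year`, `litter`, `M` (list of design matrices).
#' @return Chain state: list with `b`, `l`, `q`, `delta`, `class_var`,
#'   `sigma2_l`, `sigma2_e`.
#' @export
initialize_chain <- function(spec, data) {
  y <- data$y
  n <- length(y)
  n_year <- nlevels(data$year)
  if (n < n_year + 2) {
    stop("need at least ", n_year + 2, " observations for ", n_year,
         " birth years")
  }
  vp <- var(y)
  if (!is.finite(vp) || vp <= 0) vp <- 1
  floor_val <- 1e-12 * vp
  b <- tapply(y, data$year, mean)
  b[is.na(b)] <- mean(y)
  fixed <- spec$fixed
  cvs <- lapply(seq_along(data$M), function(t) {
    eff <- data$effects[t]
    if (!is.null(fixed$class_variances[[eff]])) {
      cv <- as.numeric(fixed$class_variances[[eff]])
    } else {
      # geometric ladder whose pi-weighted mean equals a per-SNP effect
      # variance such that the genetic effects jointly start at half the
      # phenotypic variance (matching the residual-variance initialization)
      denom <- max(sum(colSums(data$M[[t]]^2)) / n, floor_val)
      ladder <- 10^((1:4) - 2)
      cv <- (0.5 * vp / (length(data$M) * denom)) * ladder /
        sum(spec$mixing_proportions * ladder)
    }
    if (is.unsorted(cv, strictly = TRUE)) {
      stop("class variances must be strictly increasing")
    }
    pmax(cv, floor_val * (1 + 1e-6)^(0:3))
  })
  names(cvs) <- data$effects
  list(b = as.numeric(b),
       l = rep(0, nlevels(data$litter)),
       q = lapply(data$M, function(M) rep(0, ncol(M))),
       delta = lapply(data$M, function(M) rep(0L, ncol(M))),
       class_var = cvs,
       sigma2_l = if (!is.null(fixed$sigma2_l)) fixed$sigma2_l
                  else max(0.05 * vp, floor_val),
       sigma2_e = if (!is.null(fixed$sigma2_e)) fixed$sigma2_e
                  else max(0.5 * vp, floor_val))
}

# One (or a few) full Gibbs scan(s) from a given state; used by the tests to
# probe full conditionals. `update` toggles individual blocks.
gibbs_iteration <- function(state, data, spec, n_iter = 1L,
                            update = list()) {
  upd <- utils::modifyList(
    list(b = TRUE, l = TRUE,
         class_var = is.null(spec$fixed$class_variances),
         sigma2_l = is.null(spec$fixed$sigma2_l),
         sigma2_e = is.null(spec$fixed$sigma2_e)),
    update)
  vp <- var(data$y); if (!is.finite(vp) || vp <= 0) vp <- 1
  res <- .gibbs_sampler_cpp(
    data$y, as.integer(data$year) - 1L, as.integer(data$litter) - 1L,
    nlevels(data$year), nlevels(data$litter),
    data$M, spec$mixing_proportions,
    n_iter = n_iter, burn_in = 0L, thin = 1L, init = state,
    update_b = upd$b, update_l = upd$l,
    update_class_var = upd$class_var,
    update_sigma2_l = upd$sigma2_l, update_sigma2_e = upd$sigma2_e,
    var_floor = 1e-12 * vp, resync_every = 1000L)
  res$state
}

#' Fit a Bayesian mixture model by Gibbs sampling
#'
#' Runs a single Markov chain for the model
#' `y_c = Xb + M_a q_a (+ M_d q_d) (+ M_i q_i) + Z l + e` with a
#' four-component normal mixture prior on each SNP effect vector, known mixing
#' proportions, flat priors on the ordered mixture class variances and on the
#' litter and residual variances, and a flat prior on the birth-year effects.
#' Burn-in samples are discarded, the rest thinned; posterior means are the
#' reported estimates. Per-observation conditional predictive ordinates (CPO)
#' are accumulated across saved iterations by the harmonic-mean estimator, for
#' pseudo-Bayes-factor model comparison.
#'
#' @param phenotypes Tibble with columns `sample_id`, `y_c`, `litter_id`,
#'   `birth_year` (training individuals).
#' @param design A [design_matrices()] result covering the model's effects,
#'   built with the training-set allele frequencies.
#' @param spec A [model_spec].
#' @return An object of class `genomic_fit` with posterior summaries:
#'   `samples` (saved draws of all variance parameters), `snp_effects`
#'   (posterior mean and SD per SNP and effect), `cpo`, `lpml`, `convergence`
#'   (time-series SEs), and the fitted [variance_decomposition()] inputs.
#' @export
fit_genomic_mixture <- function(phenotypes, design, spec = model_spec("A")) {
  stopifnot(inherits(spec, "model_spec"))
  data <- prepare_model_data(phenotypes, design, spec$effects)
  set.seed(spec$seed)
  state <- initialize_chain(spec, data)
  vp <- var(data$y); if (!is.finite(vp) || vp <= 0) vp <- 1
  res <- .gibbs_sampler_cpp(
    data$y, as.integer(data$year) - 1L, as.integer(data$litter) - 1L,
    nlevels(data$year), nlevels(data$litter),
    data$M, spec$mixing_proportions,
    n_iter = spec$chain_length, burn_in = spec$burn_in, thin = spec$thinning,
    init = state,
    update_b = TRUE, update_l = TRUE,
    update_class_var = is.null(spec$fixed$class_variances),
    update_sigma2_l = is.null(spec$fixed$sigma2_l),
    update_sigma2_e = is.null(spec$fixed$sigma2_e),
    var_floor = 1e-12 * vp, resync_every = 1000L)

  par_names <- c("sigma2_e", "sigma2_l",
                 unlist(lapply(spec$effects, function(e)
                   paste0("v_", e, "_", 1:4))))
  samples <- res$samples
  colnames(samples) <- par_names

  snp_effects <- tibble::tibble(snp_id = data$snp_ids)
  for (t in seq_along(spec$effects)) {
    snp_effects[[paste0("q_", spec$effects[t])]] <- as.numeric(res$q_mean[[t]])
    snp_effects[[paste0("sd_", spec$effects[t])]] <- as.numeric(res$q_sd[[t]])
  }

  conv <- purrr::map_dfr(par_names, function(p) {
    if (res$n_saved >= 10) {
      se <- mcmc_standard_error(samples[, p])
    } else {
      se <- list(se = NA_real_, converged = NA, basis = NA_character_)
    }
    tibble::tibble(parameter = p, mean = mean(samples[, p]),
                   sd = sd(samples[, p]), ts_se = se$se,
                   converged = se$converged, basis = se$basis)
  })

  cpo <- tibble::tibble(sample_id = data$sample_ids,
                        cpo = as.numeric(res$cpo))
  if (any(!is.finite(cpo$cpo) | cpo$cpo <= 0)) {
    stop("invalid CPO for observation(s): ",
         paste(utils::head(cpo$sample_id[!is.finite(cpo$cpo) | cpo$cpo <= 0], 5),
               collapse = ", "))
  }

  structure(list(
    spec = spec,
    model = spec$model_name,
    effects = spec$effects,
    samples = samples,
    snp_effects = snp_effects,
    birth_year_effects = tibble::tibble(birth_year = levels(data$year),
                                        estimate = as.numeric(res$b_mean)),
    litter_effects = tibble::tibble(litter_id = levels(data$litter),
                                    estimate = as.numeric(res$l_mean)),
    cpo = cpo,
    lpml = sum(log(cpo$cpo)),
    fitted = tibble::tibble(sample_id = data$sample_ids,
                            fitted = as.numeric(res$fitted_mean)),
    convergence = conv,
    freqs = data$freqs,
    n_saved = res$n_saved,
    max_resync_diff = res$max_resync_diff,
    final_state = res$state,
    n_obs = length(data$y)), class = "genomic_fit")
}

#' @export
print.genomic_fit <- function(x, ...) {
  cat("<genomic_fit> model ", x$model, ": ", x$n_obs, " individuals, ",
      nrow(x$snp_effects), " SNPs, ", x$n_saved, " saved samples\n", sep = "")
  cat("  LPML ", format(x$lpml, digits = 6), "; ",
      sum(x$convergence$converged), "/", nrow(x$convergence),
      " variance parameters with time-series SE < 5%\n", sep = "")
  invisible(x)
}

#' @rdname fit_genomic_mixture
#' @param x,object A `genomic_fit`.
#' @param ... Unused.
#' @export
tidy.genomic_fit <- function(x, ...) {
  x$convergence |>
    dplyr::select(dplyr::all_of(c("parameter", "mean", "sd", "ts_se",
                                  "converged"))) |>
    dplyr::rename(estimate = "mean", posterior_sd = "sd")
}

#' @rdname fit_genomic_mixture
#' @export
glance.genomic_fit <- function(x, ...) {
  tibble::tibble(model = x$model, n_obs = x$n_obs,
                 n_snps = nrow(x$snp_effects), n_saved = x$n_saved,
                 lpml = x$lpml,
                 prop_converged = mean(x$convergence$converged))
}

#' Time-series standard error of an MCMC sample
#'
#' Batch-means estimate of the Monte-Carlo standard error of the posterior
#' mean, with a mixing flag: the chain is declared well mixed when the SE is
#' below 5 % of the absolute posterior mean (or of the posterior SD when the
#' mean is indistinguishable from zero; the `basis` field says which was
#' used).
#'
#' @param x Numeric vector of at least 10 saved MCMC samples.
#' @return List with `se`, `converged`, `basis` (`"mean"` or `"posterior_sd"`).
#' @export
mcmc_standard_error <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 10) stop("need at least 10 saved samples")
  n_batch <- floor(sqrt(n))
  bs <- floor(n / n_batch)
  bm <- vapply(seq_len(n_batch),
               function(i) mean(x[((i - 1) * bs + 1):(i * bs)]), 0)
  se <- sd(bm) / sqrt(n_batch)
  mu <- mean(x)
  s <- sd(x)
  # a mean buried in the posterior spread gives a meaningless relative SE;
  # judge against the posterior SD instead and say so
  if (abs(mu) >= 0.1 * s && abs(mu) > 0) {
    scale_ref <- abs(mu)
    basis <- "mean"
  } else {
    scale_ref <- s
    basis <- "posterior_sd"
  }
  converged <- if (scale_ref == 0) TRUE else (se / scale_ref) < 0.05
  list(se = se, converged = converged, basis = basis)
}

#' Predict genomic breeding values and total genetic values
#'
#' GBV is the additive prediction `M_a q_hat_a`; GTV is the sum of the
#' predictions of all genetic effects in the fitted model. Design matrices
#' must be built with the training-set allele frequencies (pass the training
#' `fit$freqs` to [design_matrices()] for validation individuals).
#'
#' @param fit A [fit_genomic_mixture()] result.
#' @param design A [design_matrices()] result for the individuals to predict.
#' @param scope `"GTV"` (all effects in the model) or `"GBV"` (additive only).
#' @return Tibble with columns `sample_id` and `value`.
#' @export
predict_genetic_values <- function(fit, design, scope = c("GTV", "GBV")) {
  scope <- match.arg(scope)
  effects <- if (scope == "GBV") "additive" else fit$effects
  need <- c(additive = "M_a", dominance = "M_d", imprinting = "M_i")[effects]
  absent <- need[!need %in% names(design)]
  if (length(absent)) {
    stop("design lacks matrices for effect(s): ",
         paste(names(absent), collapse = ", "))
  }
  value <- rep(0, length(design$sample_ids))
  for (e in effects) {
    M <- design[[c(additive = "M_a", dominance = "M_d",
                   imprinting = "M_i")[[e]]]]
    q <- fit$snp_effects[[paste0("q_", e)]]
    if (is.null(q)) stop("effect '", e, "' absent from the fitted model")
    value <- value + drop(M %*% q)
  }
  tibble::tibble(sample_id = design$sample_ids, value = unname(value))
}
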