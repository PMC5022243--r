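#' Genetic variance components from mixture class variances
#'
#' Converts the mixture-prior class variances of a fitted (or hypothesized)
#' model into genetic variances on the phenotype scale. The additive genetic
#' variance is
#' `sigma2_a = sum_j 2 p_j (1 - p_j) * sum_i pi_i * sigma2_{a,pi_i}`.
#' The dominance and imprinting analogues replace the per-SNP weight
#' `2p(1-p)` by `(2p(1-p))^2` and `2p(1-p)` respectively - each weight is the
#' variance of the corresponding coding column under Hardy-Weinberg genotype
#' frequencies (random mating for the imprinting contrast).
#'
#' `class_variances` may be a vector of 4 class variances or a matrix with 4
#' columns (one row per saved MCMC sample); with a matrix, one genetic
#' variance per sample is returned, so posterior means of the components are
#' means of the per-sample values.
#'
#' @param mixing_proportions Four mixture proportions summing to 1.
#' @param class_variances Numeric vector of length 4, or a samples x 4 matrix.
#' @param freqs Allele frequencies of the SNPs in the model.
#' @return A scalar (vector input) or vector (matrix input) of variances.
#' @export
additive_variance <- function(mixing_proportions, class_variances, freqs) {
  scaled_mixture_variance(mixing_proportions, class_variances,
                          2 * freqs * (1 - freqs))
}

#' @rdname additive_variance
#' @export
dominance_variance <- function(mixing_proportions, class_variances, freqs) {
  scaled_mixture_variance(mixing_proportions, class_variances,
                          (2 * freqs * (1 - freqs))^2)
}

#' @rdname additive_variance
#' @export
imprinting_variance <- function(mixing_proportions, class_variances, freqs) {
  scaled_mixture_variance(mixing_proportions, class_variances,
                          2 * freqs * (1 - freqs))
}

scaled_mixture_variance <- function(pi, cv, weights) {
  if (is.matrix(cv)) {
    if (ncol(cv) != length(pi)) {
      stop("class_variances must have one column per mixing proportion")
    }
    return(sum(weights) * drop(cv %*% pi))
  }
  if (length(cv) != length(pi)) {
    stop("class_variances and mixing_proportions lengths differ")
  }
  if (any(cv < 0)) stop("class variances must be >= 0")
  sum(weights) * sum(pi * cv)
}

#' Variance proportions and heritabilities
#'
#' Expresses each variance component as a proportion of the sum of the
#' components present in the model. The narrow-sense heritability is the
#' additive share; the broad-sense heritability is the share of the total
#' genetic variance (additive + dominance + imprinting, as present).
#'
#' @param components Named numeric vector of variance components; recognised
#'   names are `litter`, `additive`, `dominance`, `imprinting`, `residual`
#'   (any subset, at least one positive).
#' @return List with `proportions` (tibble: component, variance, proportion),
#'   `narrow_h2` and `broad_H2`.
#' @export
heritabilities <- function(components) {
  known <- c("litter", "additive", "dominance", "imprinting", "residual")
  if (is.null(names(components)) || !all(names(components) %in% known)) {
    stop("components must be named among: ", paste(known, collapse = ", "))
  }
  if (any(components < 0)) stop("variance components must be >= 0")
  total <- sum(components)
  if (total <= 0) stop("total variance must be positive")
  genetic <- intersect(names(components),
                       c("additive", "dominance", "imprinting"))
  list(
    proportions = tibble::tibble(
      component = names(components),
      variance = unname(components),
      proportion = unname(components) / total),
    narrow_h2 = unname(components["additive"]) / total,
    broad_H2 = sum(components[genetic]) / total)
}

#' Posterior variance decomposition of a fitted model
#'
#' Computes, for every saved MCMC sample, the genetic variance of each effect
#' in the model from the sampled mixture class variances (see
#' [additive_variance()]), together with the sampled litter and residual
#' variances, and summarises the posterior: component estimates (posterior
#' means), posterior SDs, proportions of the phenotypic variance (the sum of
#' the components in the model) and their posterior SDs, plus narrow- and
#' broad-sense heritabilities. Proportions are computed per sample and then
#' averaged.
#'
#' @param fit A [fit_genomic_mixture()] result.
#' @return An object of class `variance_decomposition`: a tibble with columns
#'   `component`, `estimate`, `sd`, `proportion`, `proportion_sd`, and
#'   attributes `narrow_h2`, `broad_H2` (with SDs) and `model`.
#' @export
variance_decomposition <- function(fit) {
  stopifnot(inherits(fit, "genomic_fit"))
  pi <- fit$spec$mixing_proportions
  p <- fit$freqs
  fns <- list(additive = additive_variance,
              dominance = dominance_variance,
              imprinting = imprinting_variance)
  comp <- list(litter = fit$samples[, "sigma2_l"])
  for (e in fit$effects) {
    cv <- fit$samples[, paste0("v_", e, "_", 1:4), drop = FALSE]
    comp[[e]] <- fns[[e]](pi, cv, p)
  }
  comp$residual <- fit$samples[, "sigma2_e"]
  comp <- comp[c("litter", intersect(c("additive", "dominance", "imprinting"),
                                     names(comp)), "residual")]
  mat <- do.call(cbind, comp)
  total <- rowSums(mat)
  props <- mat / total
  genetic_cols <- intersect(colnames(mat),
                            c("additive", "dominance", "imprinting"))
  narrow <- props[, "additive"]
  broad <- rowSums(props[, genetic_cols, drop = FALSE])

  out <- tibble::tibble(
    component = colnames(mat),
    estimate = colMeans(mat),
    sd = apply(mat, 2, sd),
    proportion = colMeans(props),
    proportion_sd = apply(props, 2, sd))
  structure(out,
            class = c("variance_decomposition", class(out)),
            narrow_h2 = mean(narrow), narrow_h2_sd = sd(narrow),
            broad_H2 = mean(broad), broad_H2_sd = sd(broad),
            model = fit$model)
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat("Variance decomposition (model ", attr(x, "model"), ")\n", sep = "")
  NextMethod()
  cat(sprintf("narrow-sense h2 = %.3f (sd %.3f); broad-sense H2 = %.3f (sd %.3f)\n",
              attr(x, "narrow_h2"), attr(x, "narrow_h2_sd"),
              attr(x, "broad_H2"), attr(x, "broad_H2_sd")))
  invisible(x)
}
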