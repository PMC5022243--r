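#' Pseudo Bayes factor between two fitted models
#'
#' Compares models through their log pseudo-marginal likelihoods (LPML), the
#' sums of log conditional predictive ordinates over the same observations.
#' Reports `2lnK = 2 (LPML_alt - LPML_base)` with an evidence label:
#' below 0 `"negative"`, 0-2 `"weak"`, 2-6 `"positive"`, 6-10
#' `"very strong"`, above 10 `"decisive"`.
#'
#' @param cpo_alt,cpo_base Per-observation CPO vectors of the two models
#'   (same observations, same order), or `genomic_fit` objects.
#' @return Tibble with `two_ln_k` and `evidence`.
#' @export
pseudo_bayes_factor <- function(cpo_alt, cpo_base) {
  get_cpo <- function(x) if (inherits(x, "genomic_fit")) x$cpo$cpo else x
  a <- get_cpo(cpo_alt)
  b <- get_cpo(cpo_base)
  if (length(a) != length(b)) {
    stop("CPO vectors must cover the same observation set")
  }
  bad <- !is.finite(a) | !is.finite(b) | a <= 0 | b <= 0
  if (any(bad)) {
    stop("zero/non-finite CPO at observation(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  }
  k2 <- 2 * (sum(log(a)) - sum(log(b)))
  tibble::tibble(two_ln_k = k2, evidence = evidence_label(k2))
}

evidence_label <- function(two_ln_k) {
  cut(two_ln_k, breaks = c(-Inf, 0, 2, 6, 10, Inf), right = FALSE,
      labels = c("negative", "weak", "positive", "very strong", "decisive")) |>
    as.character()
}

#' Split phenotypes into training and validation sets by birth date
#'
#' Individuals born before the cutoff date go to training; those born on or
#' after it to validation. Either side empty is an error.
#'
#' @param phenotypes Tibble with `sample_id` and `birth_date` columns.
#' @param cutoff_date Cutoff (anything `as.Date()` accepts).
#' @return List of two tibbles, `train` and `validation`.
#' @export
split_by_date <- function(phenotypes, cutoff_date) {
  cutoff <- as.Date(cutoff_date)
  if (is.na(cutoff)) stop("invalid cutoff date")
  is_val <- as.Date(phenotypes$birth_date) >= cutoff
  if (all(is_val)) stop("empty training set: all born on/after the cutoff")
  if (!any(is_val)) stop("empty validation set: all born before the cutoff")
  list(train = phenotypes[!is_val, , drop = FALSE],
       validation = phenotypes[is_val, , drop = FALSE])
}

#' Reliability of genomic predictions
#'
#' Squared Pearson correlation between predictions and corrected phenotypes,
#' divided by the heritability of the corrected phenotype. By definition the
#' value is not capped at 1.
#'
#' @param predictions,y_c Numeric vectors (aligned, length >= 3, both with
#'   nonzero variance).
#' @param h2_yc Heritability of the corrected phenotype, in (0, 1].
#' @return Scalar reliability.
#' @export
reliability <- function(predictions, y_c, h2_yc) {
  stopifnot(length(predictions) == length(y_c), length(y_c) >= 3,
            h2_yc > 0, h2_yc <= 1)
  if (var(predictions) <= 0) stop("predictions have zero variance")
  if (var(y_c) <= 0) stop("phenotypes have zero variance")
  cor(predictions, y_c)^2 / h2_yc
}

#' Heritability of the corrected phenotype
#'
#' `h2_yc = sigma2_a / (sigma2_a + sigma2_l + sigma2_e)`. Used to scale
#' reliabilities; by convention it is computed once (from the additive-only
#' model A) and reused for all models so that it does not affect model
#' comparisons.
#'
#' @param sigma2_a,sigma2_l,sigma2_e Additive, litter and residual variances.
#' @return Scalar heritability.
#' @export
h2_of_corrected_phenotype <- function(sigma2_a, sigma2_l, sigma2_e) {
  denom <- sigma2_a + sigma2_l + sigma2_e
  if (denom <= 0) stop("total variance must be positive")
  sigma2_a / denom
}

#' Hotelling-Williams test for two dependent correlations
#'
#' Tests whether two correlations `r13` and `r23` that share the third
#' variable (here: two models' predictions, each correlated with the same
#' observed phenotype) differ, given the correlation `r12` between the first
#' two variables. The statistic
#' \deqn{t = (r13 - r23) \sqrt{\frac{(n-1)(1+r12)}
#'   {2\frac{n-1}{n-3}|R| + \bar r^2 (1-r12)^3}}}
#' with \eqn{|R| = 1 - r12^2 - r13^2 - r23^2 + 2 r12 r13 r23} and
#' \eqn{\bar r = (r13 + r23)/2} follows a t distribution with `n - 3` degrees
#' of freedom under the null. Two-sided p-values are reported.
#'
#' @param r13,r23 Correlations of variables 1 and 2 with the shared variable 3.
#' @param r12 Correlation between variables 1 and 2.
#' @param n Sample size (>= 4).
#' @return Tibble with `statistic`, `df`, `p_value`.
#' @export
hotelling_williams_test <- function(r13, r23, r12, n) {
  stopifnot(n >= 4, abs(r13) <= 1, abs(r23) <= 1, abs(r12) <= 1)
  detR <- 1 - r12^2 - r13^2 - r23^2 + 2 * r12 * r13 * r23
  if (detR <= -1e-12) {
    stop("inconsistent correlation triple: |R| = ", format(detR))
  }
  detR <- max(detR, 0)
  rbar <- (r13 + r23) / 2
  denom <- 2 * ((n - 1) / (n - 3)) * detR + rbar^2 * (1 - r12)^3
  tstat <- if (r13 == r23) 0 else (r13 - r23) * sqrt((n - 1) * (1 + r12) / denom)
  tibble::tibble(statistic = tstat, df = n - 3,
                 p_value = 2 * pt(abs(tstat), df = n - 3, lower.tail = FALSE))
}

#' Bias regression of phenotypes on predictions
#'
#' Ordinary least squares of the corrected phenotype on the prediction.
#' Unbiased predictions have slope 1 and intercept 0; the intercept is also
#' reported relative to the mean phenotype.
#'
#' @param y_c Corrected phenotypes.
#' @param predictions Genomic predictions (length >= 3, nonzero variance).
#' @return Tibble with `slope`, `slope_se`, `intercept`, `intercept_se`,
#'   `intercept_mean_ratio`.
#' @export
bias_regression <- function(y_c, predictions) {
  stopifnot(length(y_c) == length(predictions), length(y_c) >= 3)
  if (var(predictions) <= 0) stop("predictions have zero variance")
  fit <- lm(y_c ~ predictions)
  sm <- summary(fit)$coefficients
  mu <- mean(y_c)
  tibble::tibble(
    slope = sm["predictions", "Estimate"],
    slope_se = sm["predictions", "Std. Error"],
    intercept = sm["(Intercept)", "Estimate"],
    intercept_se = sm["(Intercept)", "Std. Error"],
    intercept_mean_ratio = if (mu != 0) sm["(Intercept)", "Estimate"] / mu
                           else NA_real_)
}

#' Validate genomic predictions on a hold-out set
#'
#' For each fitted model, predicts GBV and GTV for the validation individuals
#' (design matrices must be built with training allele frequencies), computes
#' reliabilities scaled by `h2_yc`, Hotelling-Williams p-values against the
#' baseline additive model (per scope), and bias regressions of `y_c` on the
#' predictions.
#'
#' @param fits Named list of [fit_genomic_mixture()] results (must include the
#'   baseline model named `"A"`).
#' @param validation_phenotypes Tibble of validation individuals (`sample_id`,
#'   `y_c`).
#' @param validation_design [design_matrices()] for the validation
#'   individuals, built with training-set allele frequencies.
#' @param h2_yc Heritability of the corrected phenotype (from the model-A fit
#'   on training data; see [h2_of_corrected_phenotype()]).
#' @return An object of class `validation_report`: tibble with one row per
#'   model and scope (`GTV`, `GBV`): reliability, Hotelling-Williams p-value
#'   vs model A, bias slope/intercept and SEs.
#' @export
validate_predictions <- function(fits, validation_phenotypes,
                                 validation_design, h2_yc) {
  stopifnot("A" %in% names(fits))
  y <- validation_phenotypes$y_c
  n <- length(y)
  preds <- purrr::map(fits, function(f) {
    list(GTV = predict_genetic_values(f, validation_design, "GTV"),
         GBV = predict_genetic_values(f, validation_design, "GBV"))
  })
  align <- function(p) p$value[match(validation_phenotypes$sample_id,
                                     p$sample_id)]
  rows <- purrr::map_dfr(names(fits), function(model) {
    purrr::map_dfr(c("GTV", "GBV"), function(scope) {
      v <- align(preds[[model]][[scope]])
      v_base <- align(preds[["A"]][[scope]])
      r2 <- reliability(v, y, h2_yc)
      p_vs_a <- if (model == "A") NA_real_ else {
        hw <- hotelling_williams_test(cor(v, y), cor(v_base, y),
                                      cor(v, v_base), n)
        hw$p_value
      }
      dplyr::bind_cols(
        tibble::tibble(model = model, scope = scope, n_validation = n,
                       reliability = r2, p_vs_A = p_vs_a),
        bias_regression(y, v))
    })
  })
  structure(rows, class = c("validation_report", class(rows)),
            h2_yc = h2_yc)
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Validation report (h2_yc = ",
      format(attr(x, "h2_yc"), digits = 3), ")\n", sep = "")
  NextMethod()
  invisible(x)
}
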