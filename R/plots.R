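#' Plot methods
#'
#' `autoplot()` methods for the package's result objects:
#' * `genomic_fit`: trace plots of the saved variance-parameter samples, one
#'   facet per parameter;
#' * `variance_decomposition`: variance proportions with posterior-SD error
#'   bars;
#' * `validation_report`: reliability per model and prediction scope.
#'
#' @param object The object to plot.
#' @param parameters For fits, which sampled parameters to trace (defaults to
#'   the litter/residual variances).
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-imprintgp
NULL

#' @rdname autoplot-imprintgp
#' @export
autoplot.genomic_fit <- function(object,
                                 parameters = c("sigma2_e", "sigma2_l"),
                                 ...) {
  parameters <- intersect(parameters, colnames(object$samples))
  df <- tibble::as_tibble(object$samples[, parameters, drop = FALSE]) |>
    dplyr::mutate(iteration = dplyr::row_number()) |>
    tidyr::pivot_longer(-"iteration", names_to = "parameter")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "saved sample", y = "value",
                  title = paste("Model", object$model, "variance traces"))
}

#' @rdname autoplot-imprintgp
#' @export
autoplot.variance_decomposition <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$component <- factor(df$component, levels = df$component)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$proportion)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$proportion - .data$proportion_sd,
                   ymax = .data$proportion + .data$proportion_sd),
      width = 0.25) +
    ggplot2::labs(x = NULL, y = "proportion of phenotypic variance",
                  title = paste("Model", attr(object, "model"),
                                "variance decomposition"))
}

#' @rdname autoplot-imprintgp
#' @export
autoplot.validation_report <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model, y = .data$reliability,
                                   fill = .data$scope)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "model", y = expression(r^2),
                  title = "Hold-out reliability of genomic predictions")
}
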