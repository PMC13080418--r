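# ggplot2 displays for the main result types.

#' @describeIn explained_covariance Scree plot of explained covariance.
#' @param object A `variance_decomposition`.
#' @method autoplot variance_decomposition
#' @export
autoplot.variance_decomposition <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$component, y = .data$pct_explained)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Component", y = "Explained covariance (%)") +
    ggplot2::theme_minimal()
}

#' @describeIn parallel_analysis Scree plot with the permutation-null
#'   criterion overlaid.
#' @param object A `parallel_analysis`.
#' @method autoplot parallel_analysis
#' @export
autoplot.parallel_analysis <- function(object, ...) {
  d <- tidy(object)
  thr <- if (object$criterion == "mean") d$null_mean else d$null_p95
  d$criterion_value <- thr
  ggplot2::ggplot(d, ggplot2::aes(x = .data$component)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed,
                                     shape = .data$retained)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$criterion_value),
                       linetype = "dashed") +
    ggplot2::labs(x = "Component", y = "Eigenvalue",
                  shape = "Retained",
                  title = paste0("Parallel analysis: ", object$n_factors,
                                 " factor(s)")) +
    ggplot2::theme_minimal()
}

#' @describeIn information_profile Point information, StdEM or
#'   10-item-scaled curves per inventory.
#' @param object An `information_profile`.
#' @param type `"information"`, `"stdem"` or `"scaled"`.
#' @param ... Unused.
#' @method autoplot information_profile
#' @export
autoplot.information_profile <- function(object,
                                         type = c("information", "stdem",
                                                  "scaled"), ...) {
  type <- match.arg(type)
  d <- dplyr::filter(object$curves, .data$inventory != "ALL")
  y <- switch(type, information = "point_info", stdem = "stdem",
              scaled = "scaled")
  ylab <- switch(type,
                 information = "Point test information",
                 stdem = "Standard error of measurement",
                 scaled = "Point information per 10 items")
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$theta, y = .data[[y]],
                                       colour = .data$inventory)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "General factor (SD units)", y = ylab,
                  colour = "Measure") +
    ggplot2::theme_minimal()
  if (type == "stdem") p <- p + ggplot2::coord_cartesian(ylim = c(0, 2))
  p
}

#' @describeIn rotate_bigeomin Loading heatmap of the rotated solution.
#' @param object A `bifactor_solution`.
#' @method autoplot bifactor_solution
#' @export
autoplot.bifactor_solution <- function(object, ...) {
  d <- tidy(object)
  d$item_id <- factor(d$item_id, levels = rev(rownames(object$loadings)))
  d$factor <- factor(d$factor, levels = colnames(object$loadings))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$factor, y = .data$item_id,
                                  fill = .data$loading)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Loading") +
    ggplot2::theme_minimal()
}
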