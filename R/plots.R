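#' Plot strain transients
#'
#' Global and regional strain curves over the cycle, faceted by metric.
#' @param object a [strain_transients()] tibble
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.strain_transients <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$frame, y = .data$value,
                                       colour = .data$scope)) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "frame (fraction of R-R)", y = "strain (%)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a cross-validated mean ROC curve
#'
#' @param object a [roc_cv()] result
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$mean_curve, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_line(colour = "#2166ac", linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("%s: AUC %.3f +/- %.3f",
                                  paste(object$markers, collapse = " + "),
                                  object$mean_auc, object$sd_auc)) +
    ggplot2::theme_minimal()
}

#' Plot a hyperparameter-search error surface
#'
#' @param object a [hyperparameter_search()] result
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.grid_search_result <- function(object, ...) {
  g <- object$grid
  g$sw_f <- factor(signif(g$sw, 3))
  g$be_f <- factor(signif(g$be, 3))
  ggplot2::ggplot(g, ggplot2::aes(.data$be_f, .data$sw_f,
                                  fill = .data$combined)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "combined\nerror") +
    ggplot2::labs(x = "bending-energy weight", y = "sparsity weight") +
    ggplot2::theme_minimal()
}
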