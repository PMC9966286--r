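#' Plot a response-surface grid
#'
#' Filled-contour view of a [surface_grid()] (or [desirability_grid()]).
#'
#' @param object A `surface_grid` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.surface_grid <- function(object, ...) {
  free <- setdiff(names(object), ".pred")
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data[[free[1]]], y = .data[[free[2]]], z = .data$.pred,
    fill = .data$.pred
  )) +
    ggplot2::geom_raster() +
    ggplot2::geom_contour(colour = "white", linewidth = 0.2) +
    ggplot2::scale_fill_viridis_c(name = attr(object, "response")) +
    ggplot2::labs(
      title = paste("Predicted", attr(object, "response")),
      subtitle = if (length(attr(object, "fixed"))) {
        paste(names(attr(object, "fixed")), "=", attr(object, "fixed"),
              collapse = ", ")
      }
    ) +
    ggplot2::theme_minimal()
}

#' Plot a dose-response fit
#'
#' Observed points with the fitted 4PL curve (when available) and the IC50
#' marked.
#'
#' @param object An [estimate_ic50()] result.
#' @param data The dose-response table that was fitted.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ic50_fit <- function(object, data, ...) {
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$dose, y = .data$inhibition)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::geom_vline(xintercept = object$ic50, linetype = 2) +
    ggplot2::labs(y = "% inhibition",
                  title = sprintf("IC50 = %.4g (%s)", object$ic50, object$method)) +
    ggplot2::theme_minimal()
  if (!is.null(object$parameters)) {
    par <- object$parameters
    curve <- tibble::tibble(
      dose = exp(seq(log(min(data$dose)), log(max(data$dose)), length.out = 200))
    )
    curve$inhibition <- four_pl_curve(curve$dose, par["ic50"], par["hill"],
                                      par["bottom"], par["top"])
    p <- p + ggplot2::geom_line(data = curve)
  }
  p
}

#' Plot PCA scores or loadings
#'
#' @param object An [activity_pca()] result.
#' @param matrix `"scores"` or `"loadings"`.
#' @param components Two component indices.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.activity_pca <- function(object, matrix = c("scores", "loadings"),
                                  components = c(1, 2), ...) {
  matrix <- match.arg(matrix)
  tab <- tidy(object, matrix = matrix)
  pcs <- paste0("PC", components)
  lab <- names(tab)[1]
  ggplot2::ggplot(tab, ggplot2::aes(x = .data[[pcs[1]]], y = .data[[pcs[2]]],
                                    label = .data[[lab]])) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey80") +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, size = 3) +
    ggplot2::labs(
      x = sprintf("%s (%.1f%%)", pcs[1], object$explained_percent[components[1]]),
      y = sprintf("%s (%.1f%%)", pcs[2], object$explained_percent[components[2]])
    ) +
    ggplot2::theme_minimal()
}

#' Plot a validation table
#'
#' Experimental vs predicted values with RSD annotations.
#'
#' @param data A [validate_optimum()] tibble.
#' @return A ggplot.
#' @export
plot_validation <- function(data) {
  long <- tidyr::pivot_longer(data, c("experimental", "predicted"),
                              names_to = "kind", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$response, y = .data$value,
                                     fill = .data$kind)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_text(
      data = data,
      ggplot2::aes(x = .data$response, y = pmax(.data$experimental, .data$predicted),
                   label = sprintf("RSD %.2f%%", .data$rsd_percent)),
      inherit.aes = FALSE, vjust = -0.4, size = 3
    ) +
    ggplot2::labs(y = "response value", fill = NULL) +
    ggplot2::theme_minimal()
}
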