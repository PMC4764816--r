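#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

raster_tbl <- function(grid, values) {
  ctr <- make_coordinate_layers(grid)
  tibble::tibble(
    x = as.vector(ctr$Lon), y = as.vector(ctr$Lat),
    value = as.vector(values)
  )
}

#' Plot a stock map
#'
#' @param object A `soc_stock_map`.
#' @param ... Unused.
#' @return A ggplot raster map of stock (kg/m^2).
#' @method autoplot soc_stock_map
#' @export
autoplot.soc_stock_map <- function(object, ...) {
  d <- raster_tbl(object$grid, object$values)
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = paste("SOC stock,", object$label),
      x = NULL, y = NULL, fill = expression(kg ~ m^-2)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a vertical SOC section
#'
#' @param object A `soc_section` from [vertical_section()].
#' @param ... Unused.
#' @return A ggplot depth-by-distance raster of SOC content (kg/m^3) with
#'   depth increasing downward.
#' @method autoplot soc_section
#' @export
autoplot.soc_section <- function(object, ...) {
  d <- tidyr::expand_grid(
    depth = object$depths,
    pos = seq_len(ncol(object$values))
  )
  d$value <- as.vector(object$values)
  ggplot2::ggplot(d, ggplot2::aes(.data$pos, .data$depth, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::labs(
      x = "position along section (pixels)", y = "depth (m)",
      fill = expression(kg ~ m^-3)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a fitted depth function over its observations
#'
#' @param object A `soc_fit`.
#' @param ... Unused.
#' @return A ggplot of observed horizon SOC contents (points at horizon
#'   midpoints) and the fitted step-wise exponential curve, depth downward.
#' @method autoplot soc_fit
#' @export
autoplot.soc_fit <- function(object, ...) {
  zz <- seq(0, max(object$residuals$z) * 1.05, length.out = 200)
  curve_d <- tibble::tibble(z = zz, value = evaluate_soc(object$params, zz))
  ggplot2::ggplot() +
    ggplot2::geom_path(data = curve_d, ggplot2::aes(.data$value, .data$z)) +
    ggplot2::geom_point(
      data = object$residuals,
      ggplot2::aes(.data$observed, .data$z), colour = "firebrick"
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(
      title = sprintf("Site %s (R² = %.2f)", object$site_id, object$r_squared),
      x = expression(SOC ~ content ~ (kg ~ m^-3)), y = "depth (m)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot permutation variable importance
#'
#' @param imp A [variable_importance()] tibble (single model).
#' @return A ggplot ranked bar chart.
#' @export
plot_importance <- function(imp) {
  imp <- dplyr::mutate(imp, covariate = stats::reorder(.data$covariate, .data$importance))
  ggplot2::ggplot(imp, ggplot2::aes(.data$importance, .data$covariate)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "permutation importance", y = NULL) +
    ggplot2::theme_minimal()
}
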