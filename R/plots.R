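# ggplot2 displays for the result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' ROC curve of a bootstrap prediction result
#'
#' Plots the cumulated ROC across all bootstrap replicates with the AUC
#' average in the title.
#'
#' @param object An `erosion_prediction`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot erosion_prediction
#' @export
autoplot.erosion_prediction <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8, colour = "#B2182B") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = paste(object$spec, collapse = " + "),
      subtitle = sprintf("bootstrap AUC average %.3f, 90%% CI (%.3f, %.3f)",
                         object$auc_average, object$ci90[1], object$ci90[2]),
      x = "False positive rate", y = "True positive rate"
    ) +
    ggplot2::theme_minimal()
}

#' Stress-stretch curves for a set of materials
#'
#' @param materials Named list of [material_params()] (default
#'   [default_materials()]).
#' @param directions Curve directions (for anisotropic tissues both are
#'   informative).
#' @param lambda_grid Stretch grid.
#' @return A ggplot with one curve per tissue and direction.
#' @export
plot_stress_stretch <- function(materials = default_materials(),
                                directions = c("circumferential", "axial"),
                                lambda_grid = seq(0.95, 1.25, by = 0.005)) {
  curves <- purrr::map_dfr(materials, function(p) {
    purrr::map_dfr(directions, function(d) {
      stress_stretch_curve(p, direction = d, lambda_grid = lambda_grid)
    })
  })
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$lambda, y = .data$stress_kpa,
                                       colour = .data$tissue_type,
                                       linetype = .data$direction)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_y_continuous(trans = "pseudo_log",
                                breaks = c(0, 10, 100, 1000, 10000)) +
    ggplot2::labs(x = "Stretch ratio", y = "Cauchy stress (kPa, pseudo-log)",
                  colour = "Tissue", linetype = "Direction") +
    ggplot2::theme_minimal()
}

#' Plot the contours of a cross-section slice
#'
#' @param slice A [contour_slice()].
#' @param show_erosion Highlight erosion-labeled lumen points.
#' @return A ggplot.
#' @export
plot_slice <- function(slice, show_erosion = TRUE) {
  stopifnot(inherits(slice, "contour_slice"))
  close_poly <- function(p, what) {
    if (is.null(p)) return(NULL)
    tibble::tibble(x = c(p$x, p$x[1]), y = c(p$y, p$y[1]), contour = what)
  }
  df <- dplyr::bind_rows(
    close_poly(slice$outer, "outer boundary"),
    close_poly(slice$lumen, "lumen"),
    close_poly(slice$lipid, "lipid"),
    close_poly(slice$thrombus, "thrombus")
  )
  g <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        colour = .data$contour)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", colour = NULL,
                  title = sprintf("Slice %d", slice$slice_index)) +
    ggplot2::theme_minimal()
  if (show_erosion && !is.null(slice$erosion_mask) && any(slice$erosion_mask)) {
    pts <- slice$lumen[slice$erosion_mask, ]
    g <- g + ggplot2::geom_point(data = pts, ggplot2::aes(x = .data$x, y = .data$y),
                                 inherit.aes = FALSE, colour = "#B2182B", size = 1.2)
  }
  g
}

#' Group-comparison dot plot of a summary table
#'
#' @param object A `group_summary`.
#' @param ... Unused.
#' @return A ggplot of group means with +/- 1 SD ranges per variable.
#' @method autoplot group_summary
#' @export
autoplot.group_summary <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(object, "variable", "eroded_mean", "eroded_sd",
                  "non_eroded_mean", "non_eroded_sd"),
    cols = -"variable",
    names_to = c("group", ".value"),
    names_pattern = "(eroded|non_eroded)_(mean|sd)"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$mean, y = .data$variable,
                                     colour = .data$group)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$mean - .data$sd,
                                          xmax = .data$mean + .data$sd),
                             position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::labs(x = "Group mean +/- SD (native units)", y = NULL, colour = "Group") +
    ggplot2::theme_minimal()
}
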