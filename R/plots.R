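#' Heatmap of a morphospace overlap matrix
#'
#' Tile plot of the asymmetric overlap matrix, read row-wise: each tile is
#' the fraction of the row group's morphospace inside the column group's.
#'
#' @param object An [overlap_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot overlap_matrix
#' @export
autoplot.overlap_matrix <- function(object, ...) {
  d <- tidy.overlap_matrix(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group_b, y = .data$group_a,
                                  fill = .data$overlap)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$overlap), "NA",
                     sprintf("%.2f", .data$overlap))), size = 3) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "grey85") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "inside group", y = "group", fill = "overlap") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.overlap_matrix
#' @param om An [overlap_matrix()].
#' @export
plot_overlap_matrix <- function(om) autoplot.overlap_matrix(om)

#' Morphospace scatter plot
#'
#' @param embedded Output of [embed_morphospace()].
#' @param group_col Column used to colour points.
#' @return A ggplot object.
#' @export
plot_morphospace <- function(embedded, group_col = "group") {
  ggplot2::ggplot(embedded,
                  ggplot2::aes(x = .data$tsne1, y = .data$tsne2,
                               colour = .data[[group_col]])) +
    ggplot2::geom_point(size = 0.7, alpha = 0.7) +
    ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier step plot
#'
#' @param object A [km_curves()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot km_curves
#' @export
autoplot.km_curves <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$surv,
                                       colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (days)", y = "overall survival",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.km_curves
#' @param curves A [km_curves()] tibble.
#' @export
plot_km <- function(curves) autoplot.km_curves(curves)

#' Forest plot of Cox hazard ratios
#'
#' @param object A `cox_immune_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cox_immune_fit
#' @export
autoplot.cox_immune_fit <- function(object, ...) {
  d <- object$coefficients
  ggplot2::ggplot(d, ggplot2::aes(x = .data$hr, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$hr_low,
                                         xmax = .data$hr_high),
                            height = 0.15) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "hazard ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}
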