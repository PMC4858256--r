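matrix_to_df <- function(m, value = "value") {
  df <- expand.grid(x = seq_len(nrow(m)), y = seq_len(ncol(m)))
  df[[value]] <- as.vector(m)
  df
}

#' Plot en-face maps
#'
#' Raster panels of the MIP angiogram and, when present, the vesselness
#' probability map and the binary vessel mask — the standard QC render of
#' a processed scan.
#'
#' @param object An `onh_enface`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.onh_enface <- function(object, ...) {
  parts <- list(`MIP flow` = object$mip / 255)
  if (!is.null(object$vesselness)) parts$Vesselness <- object$vesselness
  if (!is.null(object$vessel_mask)) parts$`Vessel mask` <- object$vessel_mask * 1
  df <- dplyr::bind_rows(lapply(names(parts), function(nm) {
    d <- matrix_to_df(parts[[nm]])
    d$panel <- nm
    d
  }))
  df$panel <- factor(df$panel, levels = names(parts))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~panel) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "fast axis (px)", y = "slow axis (px)", fill = NULL)
}

#' Plot a layer model
#'
#' En-face heat maps of the ILM and anterior-LC/RPE surfaces with the
#' disc margin (if delineated) overlaid as a contour.
#'
#' @param object An `onh_layer_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.onh_layer_model <- function(object, ...) {
  df <- rbind(
    cbind(matrix_to_df(object$z_ilm, "depth"), surface = "ILM"),
    cbind(matrix_to_df(object$z_alc, "depth"), surface = "anterior LC / RPE")
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$depth)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~surface) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "fast axis (px)", y = "slow axis (px)",
                  fill = "depth (samples)")
  if (!is.null(object$disc_mask)) {
    dm <- matrix_to_df(object$disc_mask * 1, "disc")
    p <- p + ggplot2::geom_contour(
      data = dm, ggplot2::aes(.data$x, .data$y, z = .data$disc),
      breaks = 0.5, colour = "white", inherit.aes = FALSE)
  }
  p
}

#' Group-wise distribution of the perfusion metrics
#'
#' Boxplots of flux, vessel area density and normalized flux by study
#' group for a simulated (or measured) cohort.
#'
#' @param cohort Cohort tibble with `group` and the three metric columns.
#' @return A ggplot object.
#' @export
plot_metrics_by_group <- function(cohort) {
  long <- tidyr::pivot_longer(
    as_tibble(cohort),
    dplyr::all_of(c("flux", "vessel_area_density", "normalized_flux")),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$group, .data$value,
                                     fill = .data$group)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "ratio (unitless)")
}

#' Scatter plot for a univariate regression
#'
#' @param object An `onh_regression`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.onh_regression <- function(object, ...) {
  df <- object$fit$model
  names(df) <- c("y", "x")
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "steelblue") +
    ggplot2::labs(
      x = object$x, y = object$y,
      subtitle = sprintf("R² = %.3f, p = %.3g",
                         object$r_squared, object$p_value))
}
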