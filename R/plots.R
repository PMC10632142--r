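#' Polar tuning-curve plot for a von Mises fit
#'
#' @param object A `vm_fit`.
#' @param ... Unused.
#' @return A ggplot: measured per-direction amplitudes (points) and the
#'   fitted von Mises curve, on polar coordinates.
#' @export
autoplot.vm_fit <- function(object, ...) {
  curve <- tibble::tibble(direction_deg = seq(0, 360, by = 2))
  curve$amplitude <- predict(object, curve$direction_deg)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$direction_deg)) +
    ggplot2::geom_line(data = curve, ggplot2::aes(y = .data$amplitude),
                       colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$amplitude)) +
    ggplot2::coord_polar(start = -pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(0, 360),
                                breaks = seq(0, 315, by = 45)) +
    ggplot2::labs(x = NULL, y = expression(Delta * F / F),
                  title = sprintf("mu = %.0f deg, kappa = %.2f",
                                  object$mu_deg, object$kappa)) +
    ggplot2::theme_minimal()
}

#' Mirrored density recovery profile plot
#'
#' Plots annulus densities against distance, mirrored about x = 0 as is
#' conventional for visualising the central exclusion well, with the
#' plateau density as a reference line. The excluded first bin is shown
#' hollow.
#'
#' @param object A `drp_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.drp_profile <- function(object, ...) {
  df <- tibble::as_tibble(object)
  mirrored <- dplyr::bind_rows(df, dplyr::mutate(df, r_mid_um = -.data$r_mid_um))
  ggplot2::ggplot(mirrored,
                  ggplot2::aes(x = .data$r_mid_um, y = .data$density_per_mm2,
                               fill = !.data$excluded)) +
    ggplot2::geom_col(width = 18, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = attr(object, "plateau_density"),
                        linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "grey30", `FALSE` = "white")) +
    ggplot2::labs(x = "distance (um)", y = "density (cells/mm^2)") +
    ggplot2::theme_classic()
}

#' Histogram of a VDRI null distribution
#'
#' @param object A `vdri_null`.
#' @param ... Unused.
#' @return A ggplot; the observed VDRI (if recorded) is drawn as a vertical
#'   line.
#' @export
autoplot.vdri_null <- function(object, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object), ggplot2::aes(x = .data$vdri)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::labs(x = "VDRI (random simulations)", y = "count") +
    ggplot2::theme_classic()
  obs <- attr(object, "observed")
  if (!is.null(obs)) {
    p <- p + ggplot2::geom_vline(xintercept = obs, colour = "firebrick")
  }
  p
}

#' Vector-sum map as a heat map
#'
#' @param object A `vs_map`.
#' @param what `"magnitude"` or `"angle"`.
#' @param ... Unused.
#' @return A ggplot raster of the requested map.
#' @export
autoplot.vs_map <- function(object, what = c("magnitude", "angle"), ...) {
  what <- match.arg(what)
  m <- if (what == "magnitude") object$magnitude else object$angle_deg
  df <- tidyr::expand_grid(y = seq_len(nrow(m)), x = seq_len(ncol(m)))
  df$value <- m[cbind(df$y, df$x)]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)", fill = what) +
    ggplot2::theme_void()
  if (what == "magnitude") {
    p + ggplot2::scale_fill_viridis_c(na.value = "black")
  } else {
    p + ggplot2::scale_fill_gradientn(
      colours = c("red", "yellow", "green", "cyan", "blue", "magenta", "red"),
      limits = c(0, 360), na.value = "black"
    )
  }
}

#' IPL depth profile plot
#'
#' @param object A `depth_profile`.
#' @param ... Unused.
#' @return A ggplot of normalized intensity against IPL depth per channel.
#' @export
autoplot.depth_profile <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$depth_pct, y = .data$intensity,
                               colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(0, 100), linetype = "dotted") +
    ggplot2::labs(x = "IPL depth (% INL -> GCL)", y = "normalized intensity") +
    ggplot2::theme_classic()
}

#' Soma mosaic plot
#'
#' @param object A `point_mosaic`.
#' @param ... Unused.
#' @return A ggplot of soma positions (coloured by component for
#'   superposed mosaics) inside the sampling window.
#' @export
autoplot.point_mosaic <- function(object, ...) {
  region <- attr(object, "region")
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$x_um, y = .data$y_um,
                               colour = factor(.data$component))) +
    ggplot2::geom_point(size = 1.5, show.legend = dplyr::n_distinct(object$component) > 1) +
    ggplot2::annotate("rect", xmin = region[1], xmax = region[2],
                      ymin = region[3], ymax = region[4],
                      fill = NA, colour = "grey40") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (um)", y = "y (um)", colour = "component") +
    ggplot2::theme_classic()
}
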