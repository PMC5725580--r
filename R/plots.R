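# ggplot2 visualizations of the result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_col
#'   geom_raster labs coord_polar scale_fill_viridis_c theme_minimal
NULL

#' @export
ggplot2::autoplot

raster_tbl <- function(m, value = "value") {
  d <- tibble(y = as.vector(row(m)), x = as.vector(col(m)),
              v = as.vector(m))
  names(d)[3] <- value
  d[is.finite(d[[value]]), ]
}

#' Plot the cos-squared angular-dependence fit
#'
#' Binned anisotropy means against orientation, with the fitted
#' `C + A cos^2(gamma - theta_d)` curve.
#'
#' @param object a `cos_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.cos_fit <- function(object, ...) {
  g <- seq(0, 180, by = 1)
  th <- if (is.na(object$theta_d)) 0 else object$theta_d
  curve <- tibble(gamma = g,
                  r = object$C + object$A * cos((g - th) * pi / 180)^2)
  ggplot(object$bins, aes(x = .data$gamma, y = .data$r_mean)) +
    geom_point(aes(size = .data$n), alpha = 0.7) +
    geom_line(data = curve, aes(y = .data$r), color = "firebrick") +
    labs(x = "orientation relative to polarization axis (deg)",
         y = "anisotropy r",
         title = sprintf("r = %.3g + %.3g cos^2(gamma - %.1f), R^2 = %.4f",
                         object$C, object$A, th, object$r_squared),
         size = "pixels") +
    theme_minimal()
}

#' Plot a radial histogram of dipole orientations
#'
#' Wedges show the intensity-weighted mean polarization factor per
#' 15-degree bin of `theta_d`; the histogram is reflected to `[180, 360)`
#' to display the dyad symmetry of the transition dipole.
#'
#' @param object a `radial_histogram`.
#' @param ... unused.
#' @return a ggplot with polar coordinates.
#' @export
autoplot.radial_histogram <- function(object, ...) {
  b <- object$bins
  refl <- b
  refl$bin_mid <- refl$bin_mid + 180
  d <- dplyr::bind_rows(b, refl)
  d$mean_p[is.na(d$mean_p)] <- 0
  ggplot(d, aes(x = .data$bin_mid, y = .data$mean_p)) +
    geom_col(width = object$bin_width, fill = "steelblue", color = "grey30") +
    coord_polar(start = -pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(0, 360),
                                breaks = seq(0, 315, by = 45)) +
    labs(x = "theta_d (deg from membrane normal)",
         y = "mean intensity-weighted p",
         title = sprintf("circular-Gaussian mean %.1f deg, sd %.1f deg (n = %d)",
                         object$mean_deg, object$sd_deg, object$n)) +
    theme_minimal()
}

#' Heat-map of an anisotropy map frame
#'
#' @param object an `anisotropy_map`.
#' @param frame frame index.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.anisotropy_map <- function(object, frame = 1, ...) {
  d <- raster_tbl(object$r[, , frame], "r")
  ggplot(d, aes(.data$x, .data$y, fill = .data$r)) +
    geom_raster() +
    scale_fill_viridis_c() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    labs(title = "emission anisotropy") +
    theme_minimal()
}

#' Flow-field speed and direction overview
#'
#' Speed heat map with a sub-sampled vector overlay (direction-to-arrow).
#'
#' @param object a `flow_field`.
#' @param frame frame-pair index.
#' @param every arrow sub-sampling stride, px.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.flow_field <- function(object, frame = 1, every = 12, ...) {
  sp <- flow_speed(object)[, , frame]
  d <- raster_tbl(sp, "speed")
  vx <- object$vx[, , frame]; vy <- object$vy[, , frame]
  ys <- seq(1, nrow(vx), by = every); xs <- seq(1, ncol(vx), by = every)
  arr <- tidyr::expand_grid(y = ys, x = xs)
  arr$vx <- vx[cbind(arr$y, arr$x)]
  arr$vy <- vy[cbind(arr$y, arr$x)]
  arr <- arr[is.finite(arr$vx), ]
  sc <- every / max(sqrt(arr$vx^2 + arr$vy^2), na.rm = TRUE) / 2
  ggplot(d, aes(.data$x, .data$y)) +
    geom_raster(aes(fill = .data$speed)) +
    ggplot2::geom_segment(data = arr,
                          aes(xend = .data$x + sc * .data$vx,
                              yend = .data$y + sc * .data$vy),
                          arrow = ggplot2::arrow(length = ggplot2::unit(3, "pt")),
                          color = "white", linewidth = 0.3) +
    scale_fill_viridis_c(name = "nm/s") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    labs(title = "optical flow") +
    theme_minimal()
}

#' Plot a tilt scan
#'
#' Ensemble dipole angle against tilt, with the measured band.
#'
#' @param object a `tilt_scan` tibble.
#' @param measured_theta_d,measured_sd optional band to draw.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.tilt_scan <- function(object, measured_theta_d = NULL,
                               measured_sd = NULL, ...) {
  p <- ggplot(object, aes(x = .data$phi, y = .data$theta_ens,
                          color = .data$consistent)) +
    geom_point(size = 2) + geom_line(color = "grey60") +
    labs(x = "tilt phi (deg)", y = "ensemble dipole angle (deg)") +
    theme_minimal()
  if (!is.null(measured_theta_d) && !is.null(measured_sd)) {
    p <- p + ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                               ymin = measured_theta_d - measured_sd,
                               ymax = measured_theta_d + measured_sd,
                               alpha = 0.15, fill = "firebrick")
  }
  p
}
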