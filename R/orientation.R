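# From anisotropy / polarization maps and masks to the orientation
# statistics: per-pixel geometric orientation, cos^2 angular-dependence
# fits, Fourier amplitude, per-ROI dipole orientations and radial
# histograms.

#' Per-pixel orientation map from a cell mask
#'
#' Assigns every in-cell pixel the orientation of the local "away from the
#' edge" direction, computed reproducibly for arbitrary cell shapes: the
#' mask is smoothed with a 3-px-radius closure, the Euclidean distance to
#' the background is computed for in-cell pixels, and the central-difference
#' gradient of that distance field gives the inward direction; its folded
#' display angle is the orientation. On a circular cell this yields an
#' orientation axis running 0-180 degrees aligned with the image x axis
#' (the excitation polarization axis): a pixel due east of the center maps
#' to 0 degrees, due north to 90 degrees. The same map defines the local
#' membrane-normal axis used both when rendering synthetic scenes and when
#' fitting, so generation and analysis share one geometry definition.
#'
#' @param cell logical cell mask (matrix; first frame used if a stack).
#' @param closure_radius smoothing closure radius in px (default 3).
#' @param smooth_sigma Gaussian smoothing of the distance field before the
#'   gradient, px. Near the boundary the raw Euclidean distance map is
#'   quantized to a few discrete values and central differences snap to the
#'   axis directions; smoothing at the scale of the closure radius keeps
#'   boundary-adjacent orientations within about 2 degrees of the true
#'   normal on a disk. 0 disables smoothing.
#' @return matrix of orientations in degrees `[0, 180)`, NA outside the cell
#'   and where the distance gradient vanishes (medial-axis ridge).
#' @export
orientation_map <- function(cell, closure_radius = 3, smooth_sigma = 3) {
  if (length(dim(cell)) == 3L) cell <- cell[, , 1]
  cell <- cell > 0
  if (!any(cell)) abort("empty cell mask")
  sm <- if (closure_radius > 0)
    EBImage::closing(cell * 1, disc_brush(closure_radius)) > 0 else cell
  d <- EBImage::distmap(sm * 1)
  if (smooth_sigma > 0) d <- EBImage::gblur(d, smooth_sigma)
  ny <- nrow(d); nx <- ncol(d)
  gx <- matrix(NA_real_, ny, nx); gy <- matrix(NA_real_, ny, nx)
  gx[, 2:(nx - 1)] <- (d[, 3:nx] - d[, 1:(nx - 2)]) / 2
  gy[2:(ny - 1), ] <- (d[3:ny, ] - d[1:(ny - 2), ]) / 2
  ori <- raster_angle(gx, gy)
  ori[!sm | !cell | (gx == 0 & gy == 0) | is.na(gx) | is.na(gy)] <- NA_real_
  ori
}

#' Fit the cos-squared angular dependence of anisotropy
#'
#' Fits \deqn{r = C + A \cos^2(\gamma - \theta_d)} to per-pixel anisotropy
#' `r` against per-pixel orientation `gamma`. Orientations are binned to the
#' closest `bin_width` degrees; by default the fit runs on count-weighted
#' bin means (`mode = "binned"`), which is what makes noiseless ideal images
#' fit with R^2 = 1; `mode = "pixels"` fits every pixel against its snapped
#' orientation instead. Because the model is exactly linear in
#' `(1, cos 2*gamma, sin 2*gamma)`, the fit is closed-form harmonic
#' regression: no iterative optimizer, no local optima, and `A >= 0`,
#' `theta_d` in `[0, 180)` by construction.
#'
#' @param r numeric vector of anisotropy (or polarization-factor) values.
#' @param gamma numeric vector of orientations, degrees.
#' @param bin_width 10 or 15 degrees (any positive divisor of 180 accepted).
#' @param mode `"binned"` (fit bin means, default) or `"pixels"`.
#' @param min_span minimum angular coverage of occupied bins, degrees.
#' @return object of class `cos_fit`: `C`, `A`, `theta_d`, `r_squared`,
#'   `n_pixels`, `n_bins`, `status` (`"ok"` or `"degenerate"`), and the
#'   binned data as a tibble.
#' @export
cos2_fit <- function(r, gamma, bin_width = 10,
                     mode = c("binned", "pixels"), min_span = 90) {
  mode <- match.arg(mode)
  ok <- is.finite(r) & is.finite(gamma)
  r <- r[ok]; gamma <- fold180(gamma[ok])
  if (length(r) < 3L) abort("too few valid pixels for the cos^2 fit")
  centers <- fold180(round(gamma / bin_width) * bin_width)
  occ <- sort(unique(centers))
  if (length(occ) >= 2L) {
    gaps <- diff(c(occ, occ[1] + 180))
    span <- 180 - max(gaps)
  } else span <- 0
  if (length(occ) < 3L || span < min_span)
    abort(sprintf("insufficient angular coverage (%d bins spanning %.0f deg)",
                  length(occ), span))
  bins <- dplyr::summarise(
    dplyr::group_by(tibble(gamma = centers, r = r), .data$gamma),
    r_mean = mean(.data$r), n = dplyr::n(), .groups = "drop")
  if (mode == "binned") {
    g <- bins$gamma; y <- bins$r_mean; w <- bins$n
  } else {
    g <- centers; y <- r; w <- rep(1, length(r))
  }
  g2 <- 2 * g * pi / 180
  X <- cbind(1, cos(g2), sin(g2))
  fit <- stats::lm.wfit(X, y, w)
  a <- fit$coefficients
  A <- unname(2 * sqrt(a[2]^2 + a[3]^2))
  theta_d <- unname(fold180(0.5 * atan2(a[3], a[2]) * 180 / pi))
  C <- unname(a[1] - A / 2)
  mu <- sum(w * y) / sum(w)
  ss_tot <- sum(w * (y - mu)^2)
  ss_res <- sum(w * fit$residuals^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  status <- "ok"
  if (!is.finite(A) || A < 1e-4 || !is.finite(r2)) {
    status <- "degenerate"
    if (A < 1e-4) theta_d <- NA_real_
  }
  structure(list(C = unname(C), A = unname(A), theta_d = theta_d,
                 r_squared = r2, n_pixels = length(r),
                 n_bins = nrow(bins), bin_width = bin_width, mode = mode,
                 status = status, bins = bins),
            class = "cos_fit")
}

#' @export
print.cos_fit <- function(x, ...) {
  cat(sprintf(
    "<cos_fit> r = C + A cos^2(gamma - theta_d): C = %.4g, A = %.4g, theta_d = %s, R^2 = %s (%s, %d px, %d bins)\n",
    x$C, x$A, if (is.na(x$theta_d)) "NA" else sprintf("%.2f deg", x$theta_d),
    if (is.na(x$r_squared)) "NA" else sprintf("%.4f", x$r_squared),
    x$status, x$n_pixels, x$n_bins))
  invisible(x)
}

#' @export
tidy.cos_fit <- function(x, ...) {
  tibble(term = c("C", "A", "theta_d"),
         estimate = c(x$C, x$A, x$theta_d))
}

#' @export
glance.cos_fit <- function(x, ...) {
  tibble(C = x$C, A = x$A, theta_d = x$theta_d, r_squared = x$r_squared,
         n_pixels = x$n_pixels, n_bins = x$n_bins, status = x$status)
}

#' @export
augment.cos_fit <- function(x, ...) {
  g2 <- 2 * x$bins$gamma * pi / 180
  dplyr::mutate(x$bins,
                .fitted = x$C + x$A * cos((x$bins$gamma - ifelse(is.na(x$theta_d), 0, x$theta_d)) * pi / 180)^2)
}

#' Fourier estimate of the angular-dependence amplitude
#'
#' An alternative to [cos2_fit]: the running average of anisotropy over
#' orientation is computed on a uniform 1-degree grid over `[0, 180)` with a
#' circular boxcar window, the mean (DC term) is subtracted, and the
#' magnitude of the first non-DC harmonic of the discrete Fourier transform
#' is returned. For `r = C + A cos^2(gamma - theta_d)` the identity
#' `cos^2 x = 1/2 + cos(2x)/2` makes this amplitude equal `A / 2`.
#'
#' @param r,gamma as in [cos2_fit].
#' @param grid_step angular grid step, degrees.
#' @param window boxcar running-average window, degrees (default 10).
#' @return tibble with `amplitude`, `phase_deg` (orientation of the
#'   harmonic maximum, `[0,180)`), and `interpolated_fraction` (share of
#'   grid cells with no data, filled by circular interpolation; > 0 flags
#'   gappy angular coverage).
#' @export
fourier_amplitude <- function(r, gamma, grid_step = 1, window = 10) {
  ok <- is.finite(r) & is.finite(gamma)
  r <- r[ok]; gamma <- fold180(gamma[ok])
  if (length(r) < 3L) abort("too few valid pixels")
  grid <- seq(0, 180 - grid_step, by = grid_step)
  half <- window / 2
  avg <- vapply(grid, function(g) {
    d <- circ_dist180(gamma, g)
    sel <- d <= half
    if (any(sel)) mean(r[sel]) else NA_real_
  }, numeric(1))
  n_na <- sum(is.na(avg))
  if (n_na > 0) {
    idx <- seq_along(avg)
    present <- which(!is.na(avg))
    if (length(present) < 2L) abort("angular coverage too sparse")
    # circular linear interpolation across gaps
    xp <- c(present, present[1] + length(avg))
    yp <- c(avg[present], avg[present[1]])
    avg[-present] <- stats::approx(xp, yp, xout = ifelse(idx[-present] < present[1],
                                                        idx[-present] + length(avg),
                                                        idx[-present]))$y
  }
  z <- stats::fft(avg - mean(avg))
  amplitude <- 2 * Mod(z[2]) / length(avg)
  phase <- fold180(-Arg(z[2]) * 180 / (2 * pi))
  tibble(amplitude = amplitude, phase_deg = phase,
         interpolated_fraction = n_na / length(avg))
}

#' Dipole orientation of boundary ROIs from a calibrated four-channel stack
#'
#' Sums the background-corrected channel intensities over each ROI, computes
#' the dipole orientation and polarization factor from the sums
#' ([quad_polarization]), and expresses the orientation relative to the
#' ROI's membrane normal: `theta_d = (theta_abs - normal) mod 180`,
#' counter-clockwise from the normal. Zero-intensity ROIs are kept in the
#' table with `status = "skipped"`.
#'
#' @param quad a calibrated [quad_stack].
#' @param rois a [boundary_rois] tibble.
#' @param frame frame index to analyze.
#' @return tibble of class `segment_dipoles`: `roi_id`, `kind`,
#'   `theta_abs`, `theta_d`, `p`, `total_intensity`, `n_pixels`, `status`.
#' @export
segment_dipole <- function(quad, rois, frame = 1L) {
  stopifnot(inherits(quad, "quad_stack"))
  if (!quad$calibrated)
    warn("quad stack is not flagged as calibrated; orientations may be biased")
  dims <- dim(quad$I0)[1:2]
  ch <- lapply(c("I0", "I45", "I90", "I135"), function(k) quad[[k]][, , frame])
  rows <- purrr::pmap(rois, function(...) {
    roi <- tibble(...)
    m <- roi_mask(roi, dims)
    n_px <- sum(m)
    sums <- vapply(ch, function(f) sum(f[m]), numeric(1))
    if (n_px == 0L || sum(sums) <= 0) {
      return(tibble(roi_id = roi$roi_id, kind = roi$kind,
                    theta_abs = NA_real_, theta_d = NA_real_, p = NA_real_,
                    total_intensity = sum(sums), n_pixels = n_px,
                    status = "skipped"))
    }
    qp <- quad_polarization(sums[1], sums[2], sums[3], sums[4])
    theta_d <- if (is.na(qp$theta_deg)) NA_real_ else
      fold180(qp$theta_deg - roi$normal_deg)
    tibble(roi_id = roi$roi_id, kind = roi$kind,
           theta_abs = qp$theta_deg, theta_d = theta_d, p = qp$p,
           total_intensity = qp$total, n_pixels = n_px,
           status = if (qp$isotropic) "isotropic" else "ok")
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("segment_dipoles", class(out))
  out
}

#' Radial histogram of segment dipole orientations
#'
#' Bins `theta_d` (dipole angle from the membrane normal) into 15-degree
#' wedges over `[0, 180)`, reporting the intensity-weighted mean
#' polarization factor per wedge, and fits a circular Gaussian (wrapped
#' normal on the 180-degree orientation circle, moment estimator on doubled
#' angles) to the intensity-weighted `theta_d` values. For display the
#' histogram is reflected to `[180, 360)` to honor the dyad symmetry of the
#' dipole.
#'
#' @param segments a `segment_dipoles` tibble (rows with `status != "ok"`
#'   are dropped).
#' @param bin_width wedge width, degrees.
#' @param weight `"intensity"` (default) or `"equal"`.
#' @return object of class `radial_histogram`: tibble of bins plus fit
#'   fields `mean_deg`, `sd_deg`, `resultant`, `n`.
#' @export
radial_histogram <- function(segments, bin_width = 15,
                             weight = c("intensity", "equal")) {
  weight <- match.arg(weight)
  seg <- segments[segments$status == "ok" & is.finite(segments$theta_d), ]
  if (nrow(seg) == 0L) abort("no usable segments for the radial histogram")
  w <- if (weight == "intensity") seg$total_intensity else rep(1, nrow(seg))
  edges <- seq(0, 180, by = bin_width)
  idx <- findInterval(fold180(seg$theta_d), edges, rightmost.closed = FALSE)
  bins <- tibble(bin_start = edges[-length(edges)],
                 bin_mid = edges[-length(edges)] + bin_width / 2)
  agg <- dplyr::summarise(
    dplyr::group_by(tibble(idx = idx, p = seg$p, w = w), .data$idx),
    mean_p = sum(.data$p * .data$w) / sum(.data$w),
    n = dplyr::n(), w_sum = sum(.data$w), .groups = "drop")
  bins$mean_p <- NA_real_; bins$n <- 0L; bins$w_sum <- 0
  bins$mean_p[agg$idx] <- agg$mean_p
  bins$n[agg$idx] <- agg$n
  bins$w_sum[agg$idx] <- agg$w_sum
  fit <- circular_mean180(seg$theta_d, w)
  structure(list(bins = bins, mean_deg = fit$mean, sd_deg = fit$sd,
                 resultant = fit$resultant, n = nrow(seg),
                 bin_width = bin_width, weight = weight),
            class = "radial_histogram")
}

#' @export
print.radial_histogram <- function(x, ...) {
  cat(sprintf("<radial_histogram> %d segments, circular-Gaussian mean = %.1f deg, sd = %.1f deg\n",
              x$n, x$mean_deg, x$sd_deg))
  invisible(x)
}

#' @export
glance.radial_histogram <- function(x, ...) {
  tibble(mean_deg = x$mean_deg, sd_deg = x$sd_deg,
         resultant = x$resultant, n = x$n)
}

#' @export
tidy.radial_histogram <- function(x, ...) x$bins

#' Per-region cos-squared fits of an anisotropy map
#'
#' Convenience wrapper running [orientation_map] once on the cell mask and
#' [cos2_fit] on each region of interest (cell, edge, protrusion, leading
#' edge), with the SNR-5 exclusion rule applied per region.
#'
#' @param amap an `anisotropy_map`.
#' @param regions named list of logical masks (matrices or stacks; frame
#'   `frame` is used).
#' @param cell_mask mask defining the orientation map (defaults to
#'   `regions$cell`).
#' @param bg optional `background_model` for the SNR gate; `NULL` skips it.
#' @param perp optional perpendicular-channel stack for the SNR numerator.
#' @param frame frame index.
#' @inheritParams cos2_fit
#' @return tibble: one row per region with the `cos_fit` parameters, SNR
#'   and status (`"low_snr"` rows carry NA parameters).
#' @export
region_cos_fits <- function(amap, regions, cell_mask = regions$cell,
                            bg = NULL, perp = NULL, frame = 1L,
                            bin_width = 10, mode = c("binned", "pixels")) {
  mode <- match.arg(mode)
  stopifnot(inherits(amap, "anisotropy_map"))
  get_frame <- function(m) if (length(dim(m)) == 3L) m[, , frame] else m
  ori <- orientation_map(get_frame(cell_mask))
  r <- amap$r[, , frame]
  valid <- amap$valid[, , frame]
  purrr::map_dfr(names(regions), function(nm) {
    m <- get_frame(regions[[nm]]) & valid
    snr <- NA_real_
    if (!is.null(bg) && !is.null(perp) && any(m))
      snr <- region_snr(get_frame(perp)[m], bg)
    base <- tibble(region = nm, C = NA_real_, A = NA_real_,
                   theta_d = NA_real_, r_squared = NA_real_,
                   n_pixels = sum(m), snr = snr, status = NA_character_)
    if (!any(m)) { base$status <- "empty"; return(base) }
    if (is.finite(snr) && snr < 5) { base$status <- "low_snr"; return(base) }
    fit <- tryCatch(cos2_fit(r[m], ori[m], bin_width = bin_width, mode = mode),
                    error = function(e) NULL)
    if (is.null(fit)) { base$status <- "no_coverage"; return(base) }
    tibble(region = nm, C = fit$C, A = fit$A, theta_d = fit$theta_d,
           r_squared = fit$r_squared, n_pixels = fit$n_pixels, snr = snr,
           status = fit$status)
  })
}
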