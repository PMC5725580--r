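# Optical-flow quantification of actin texture movies: per-pixel
# Lucas-Kanade flow, per-ROI speed and direction relative to the membrane
# tangent, direction histograms, and kymograph-slope velocimetry.

box_filter <- function(m, size) {
  EBImage::filter2(m, matrix(1, size, size), boundary = "replicate")
}

halve <- function(m) {
  ny <- 2 * (nrow(m) %/% 2); nx <- 2 * (ncol(m) %/% 2)
  m <- m[seq_len(ny), seq_len(nx)]
  (m[seq(1, ny, 2), seq(1, nx, 2)] + m[seq(2, ny, 2), seq(1, nx, 2)] +
     m[seq(1, ny, 2), seq(2, nx, 2)] + m[seq(2, ny, 2), seq(2, nx, 2)]) / 4
}

warp_by <- function(m, vx, vy) {
  # sample m at positions displaced by -(vx, vy): pattern moved forward by v
  ny <- nrow(m); nx <- ncol(m)
  X <- matrix(rep(seq_len(nx), each = ny), ny, nx)
  Y <- matrix(rep(seq_len(ny), nx), ny, nx)
  matrix(bilinear_sample(m, as.numeric(X - vx), as.numeric(Y - vy)), ny, nx)
}

lk_pair <- function(f1, f2, window) {
  # filter2 is a convolution (kernel flipped); this yields central differences
  gxk <- matrix(c(0.5, 0, -0.5), 1, 3)
  Ix <- EBImage::filter2((f1 + f2) / 2, gxk, boundary = "replicate")
  Iy <- EBImage::filter2((f1 + f2) / 2, t(gxk), boundary = "replicate")
  It <- f2 - f1
  Sxx <- box_filter(Ix * Ix, window); Syy <- box_filter(Iy * Iy, window)
  Sxy <- box_filter(Ix * Iy, window)
  Sxt <- box_filter(Ix * It, window); Syt <- box_filter(Iy * It, window)
  det <- Sxx * Syy - Sxy^2
  tr <- Sxx + Syy
  min_eig <- tr / 2 - sqrt(pmax(tr^2 / 4 - det, 0))
  ok <- det > .Machine$double.eps
  vx <- matrix(0, nrow(f1), ncol(f1)); vy <- vx
  vx[ok] <- (-Syy[ok] * Sxt[ok] + Sxy[ok] * Syt[ok]) / det[ok]
  vy[ok] <- (Sxy[ok] * Sxt[ok] - Sxx[ok] * Syt[ok]) / det[ok]
  list(vx = vx, vy = vy, min_eig = min_eig)
}

#' Lucas-Kanade optical flow of a texture movie
#'
#' Window-based least-squares solution of the brightness-constancy
#' equations for each pixel of each frame pair, with a coarse-to-fine
#' pyramid (each level halves the resolution) and one warped refinement
#' pass per level so displacements of a few pixels are recovered without
#' bias. Pixels whose structure tensor is ill-conditioned (smallest
#' eigenvalue below `min_eig_frac` of the stack's maximum) are masked
#' rather than reported as zero; a textureless movie therefore yields a
#' fully masked field.
#'
#' @param stack `ny x nx x n_frames` array, `n_frames >= 2`.
#' @param window odd LK window size, px (default 15).
#' @param n_levels pyramid levels (default 2).
#' @param min_eig_frac confidence threshold as a fraction of the maximum
#'   smallest-eigenvalue over the stack.
#' @param pixel_size nm; @param frame_interval s.
#' @return object of class `flow_field`: arrays `vx`, `vy` (px/frame,
#'   pattern displacement in raster coordinates), `valid`, and the
#'   conversion metadata. Speeds in nm/s are `|v| * pixel_size /
#'   frame_interval`.
#' @export
lucas_kanade_flow <- function(stack, window = 15, n_levels = 2,
                              min_eig_frac = 0.01,
                              pixel_size = 109, frame_interval = 1) {
  stack <- as_stack(stack, "movie")
  nf <- dim(stack)[3]
  if (nf < 2L) abort("need at least 2 frames")
  ny <- dim(stack)[1]; nx <- dim(stack)[2]
  vx <- array(0, c(ny, nx, nf - 1)); vy <- vx
  conf <- array(0, c(ny, nx, nf - 1))
  for (i in seq_len(nf - 1L)) {
    pyr1 <- list(stack[, , i]); pyr2 <- list(stack[, , i + 1])
    for (l in seq_len(n_levels - 1L)) {
      pyr1[[l + 1L]] <- halve(pyr1[[l]]); pyr2[[l + 1L]] <- halve(pyr2[[l]])
    }
    ux <- matrix(0, nrow(pyr1[[n_levels]]), ncol(pyr1[[n_levels]])); uy <- ux
    for (l in rev(seq_len(n_levels))) {
      f1 <- pyr1[[l]]; f2 <- pyr2[[l]]
      if (l < n_levels) {
        ux <- 2 * EBImage::resize(ux, w = nrow(f1), h = ncol(f1))
        uy <- 2 * EBImage::resize(uy, w = nrow(f1), h = ncol(f1))
      }
      for (pass in 1:2) {
        f1w <- warp_by(f1, ux, uy)
        res <- lk_pair(f1w, f2, window)
        ux <- ux + res$vx; uy <- uy + res$vy
      }
      if (l == 1L) conf[, , i] <- res$min_eig
    }
    vx[, , i] <- ux; vy[, , i] <- uy
  }
  thr <- min_eig_frac * max(conf)
  valid <- conf > thr & max(conf) > 0
  vx[!valid] <- NA_real_; vy[!valid] <- NA_real_
  structure(list(vx = vx, vy = vy, valid = valid, confidence = conf,
                 pixel_size = pixel_size, frame_interval = frame_interval,
                 params = list(window = window, n_levels = n_levels,
                               min_eig_frac = min_eig_frac)),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  sp <- flow_speed(x)
  cat(sprintf("<flow_field> %d x %d px, %d frame pair(s), %.1f%% valid, median speed %.3g nm/s\n",
              dim(x$vx)[1], dim(x$vx)[2], dim(x$vx)[3], 100 * mean(x$valid),
              stats::median(sp, na.rm = TRUE)))
  invisible(x)
}

#' Per-pixel flow speed in nm/s
#' @param field a `flow_field`.
#' @return array of speeds (NA on masked pixels).
#' @export
flow_speed <- function(field) {
  sqrt(field$vx^2 + field$vy^2) * field$pixel_size / field$frame_interval
}

#' Average flow per boundary ROI, relative to the membrane tangent
#'
#' Vector-averages the velocity within each ROI (the vector mean, not the
#' mean of angles, avoiding wraparound bias), converts speed to nm/s, and
#' reports the flow direction relative to the membrane tangent as
#' `(flow angle - tangent angle) mod 180`. Fully masked ROIs are kept with
#' `status = "skipped"`.
#'
#' @param field a `flow_field`.
#' @param rois a [boundary_rois] tibble on the same pixel grid.
#' @return tibble of class `segment_flow`: `roi_id`, `kind`, `speed_nm_s`,
#'   `flow_deg` (display convention, `[0,360)`), `angle_to_tangent`
#'   (`[0,180)`), `n_pixels`, `status`.
#' @export
flow_by_segment <- function(field, rois) {
  dims <- dim(field$vx)[1:2]
  rows <- purrr::pmap(rois, function(...) {
    roi <- tibble(...)
    m <- roi_mask(roi, dims)
    sel <- rep(m, dim(field$vx)[3]) & field$valid
    n <- sum(sel)
    if (n == 0L) {
      return(tibble(roi_id = roi$roi_id, kind = roi$kind,
                    speed_nm_s = NA_real_, flow_deg = NA_real_,
                    angle_to_tangent = NA_real_, n_pixels = 0L,
                    status = "skipped"))
    }
    mvx <- mean(field$vx[sel]); mvy <- mean(field$vy[sel])
    speed <- sqrt(mvx^2 + mvy^2) * field$pixel_size / field$frame_interval
    flow_deg <- (atan2(-mvy, mvx) * 180 / pi) %% 360
    tibble(roi_id = roi$roi_id, kind = roi$kind, speed_nm_s = speed,
           flow_deg = flow_deg,
           angle_to_tangent = fold180(flow_deg - roi$tangent_deg),
           n_pixels = n, status = "ok")
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("segment_flow", class(out))
  out
}

#' Histogram of flow directions relative to the tangent, with Gaussian fit
#'
#' Bins the per-segment `angle_to_tangent` values into 15-degree bins over
#' `[0, 180)` and fits a Gaussian to the bin counts by least squares,
#' reporting the fitted mean alongside the sample mean +/- SEM. Degenerate
#' (single-bin) data yield the point estimate with the fit skipped; a flat
#' (uniform) distribution is reported with its poor fit R^2.
#'
#' @param segments a `segment_flow` tibble (or numeric vector of angles).
#' @param bin_width degrees.
#' @param min_segments minimum rows required.
#' @return list of class `direction_histogram`: `bins` tibble, `fit_mean`,
#'   `fit_sd`, `fit_r_squared`, `sample_mean`, `sample_sem`, `n`, `status`.
#' @export
direction_histogram <- function(segments, bin_width = 15, min_segments = 10) {
  ang <- if (is.numeric(segments)) segments else segments$angle_to_tangent
  ang <- fold180(ang[is.finite(ang)])
  if (length(ang) < min_segments)
    abort(sprintf("need at least %d segments", min_segments))
  edges <- seq(0, 180, by = bin_width)
  idx <- findInterval(ang, edges, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  mids <- edges[-length(edges)] + bin_width / 2
  bins <- tibble(bin_mid = mids, count = counts)
  sample_mean <- mean(ang)
  sample_sem <- stats::sd(ang) / sqrt(length(ang))
  status <- "ok"
  fit_mean <- fit_sd <- fit_r2 <- NA_real_
  if (sum(counts > 0) <= 1L) {
    status <- "single_bin"
    fit_mean <- sample_mean; fit_sd <- 0
  } else {
    st <- list(A = max(counts), mu = sample_mean,
               s = max(stats::sd(ang), bin_width / 2))
    fit <- tryCatch(
      stats::nls(count ~ A * exp(-(bin_mid - mu)^2 / (2 * s^2)),
                 data = bins, start = st,
                 control = stats::nls.control(warnOnly = TRUE)),
      error = function(e) NULL)
    if (is.null(fit)) {
      status <- "no_fit"
    } else {
      cf <- coef(fit)
      fit_mean <- unname(cf["mu"]); fit_sd <- abs(unname(cf["s"]))
      ss_res <- sum(stats::resid(fit)^2)
      ss_tot <- sum((counts - mean(counts))^2)
      fit_r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
      if (is.finite(fit_r2) && fit_r2 < 0.5) status <- "poor_fit"
    }
  }
  structure(list(bins = bins, fit_mean = fit_mean, fit_sd = fit_sd,
                 fit_r_squared = fit_r2, sample_mean = sample_mean,
                 sample_sem = sample_sem, n = length(ang), status = status),
            class = "direction_histogram")
}

#' @export
print.direction_histogram <- function(x, ...) {
  cat(sprintf("<direction_histogram> n = %d, fit mean = %s deg, sample mean = %.1f +/- %.2f deg (%s)\n",
              x$n, if (is.na(x$fit_mean)) "NA" else sprintf("%.1f", x$fit_mean),
              x$sample_mean, x$sample_sem, x$status))
  invisible(x)
}

#' @export
glance.direction_histogram <- function(x, ...) {
  tibble(fit_mean = x$fit_mean, fit_sd = x$fit_sd,
         fit_r_squared = x$fit_r_squared, sample_mean = x$sample_mean,
         sample_sem = x$sample_sem, n = x$n, status = x$status)
}

#' Velocity from the streak slope of a kymograph
#'
#' Builds the space-time image along a sampling line and estimates the
#' dominant streak slope by angular maximization of line integrals: the
#' kymograph rows are sheared by candidate velocities and the variance of
#' the column means is maximized (a Radon-style criterion — streaks aligned
#' vertically after shearing by the true velocity concentrate the signal),
#' with parabolic sub-sample refinement. Speed is `|slope| * pixel_size /
#' frame_interval`.
#'
#' @param stack movie array, at least 10 frames.
#' @param line list or vector `c(x0, y0, x1, y1)` in px.
#' @param pixel_size nm; @param frame_interval s.
#' @param max_speed_px largest |velocity| searched, px/frame.
#' @param step_px search grid step, px/frame.
#' @return tibble with `speed_nm_s`, `slope_px_per_frame` (signed, positive
#'   toward the line's (x1,y1) end), and `contrast` (peak-to-mean score
#'   ratio; an error is raised when no dominant orientation exists).
#' @export
kymograph_velocity <- function(stack, line, pixel_size = 109,
                               frame_interval = 1, max_speed_px = 4,
                               step_px = 0.1) {
  stack <- as_stack(stack, "movie")
  nf <- dim(stack)[3]
  if (nf < 10L) abort("kymograph analysis needs at least 10 frames")
  line <- as.numeric(unlist(line))
  len <- sqrt((line[3] - line[1])^2 + (line[4] - line[2])^2)
  ns <- max(8L, ceiling(len))
  sx <- seq(line[1], line[3], length.out = ns)
  sy <- seq(line[2], line[4], length.out = ns)
  K <- matrix(0, nf, ns)
  for (i in seq_len(nf)) K[i, ] <- bilinear_sample(stack[, , i], sx, sy)
  K <- K - mean(K)
  vs <- seq(-max_speed_px, max_speed_px, by = step_px)
  score <- vapply(vs, function(v) {
    pos <- seq_len(ns)
    shifted <- vapply(seq_len(nf), function(t)
      stats::approx(pos, K[t, ], xout = pos + v * (t - 1), rule = 1)$y,
      numeric(ns))
    cm <- rowMeans(shifted, na.rm = TRUE)
    nobs <- rowSums(!is.na(shifted))
    stats::var(cm[nobs >= nf / 2], na.rm = TRUE)
  }, numeric(1))
  peak <- which.max(score)
  # a genuine streak produces a broad high plateau around the best shear;
  # uncorrelated noise produces isolated single-candidate spikes, so the
  # local mean around the peak discriminates the two
  nb <- max(1, peak - 3):min(length(score), peak + 3)
  contrast <- mean(score[nb]) / mean(score)
  if (!is.finite(contrast) || contrast < 1.5)
    abort("no dominant streak orientation in the kymograph")
  v <- vs[peak]
  if (peak > 1L && peak < length(vs)) {
    y1 <- score[peak - 1]; y2 <- score[peak]; y3 <- score[peak + 1]
    denom <- y1 - 2 * y2 + y3
    if (denom < 0) v <- v + step_px * 0.5 * (y1 - y3) / denom
  }
  tibble(speed_nm_s = abs(v) * pixel_size / frame_interval,
         slope_px_per_frame = v, contrast = contrast)
}
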