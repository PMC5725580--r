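# Core polarization math shared by the two-channel (anisotropy) and
# four-channel (dipole orientation / polarization factor) modalities.

#' Estimate the camera background from the image histogram
#'
#' The background intensity distribution is estimated by fitting the left
#' half of a Gaussian (the portion below its mean) to the left shoulder of
#' the image intensity histogram. Bright foreground pixels populate only the
#' right tail and therefore do not bias the estimate. The background mask
#' threshold is set 3 standard deviations above the fitted mean.
#'
#' @param image numeric matrix or array of intensities (all frames pooled).
#' @param nbins number of histogram bins.
#' @return object of class `background_model`: list with `mu`, `sigma`,
#'   `threshold` (`mu + 3*sigma`) and `mask` (logical, TRUE on background
#'   pixels, same dimensions as `image`).
#' @export
estimate_background <- function(image, nbins = 128) {
  v <- as.numeric(image)
  v <- v[is.finite(v)]
  if (length(v) < 1000L)
    abort("need at least 1000 finite pixels to estimate the background")
  if (stats::sd(v) == 0) {
    mu <- v[1]; sigma <- 0
  } else {
    # two-pass histogram: a coarse pass locates the background peak, a fine
    # pass restricted to its neighborhood resolves the left shoulder even
    # when bright foreground stretches the intensity range by orders of
    # magnitude
    h0 <- graphics::hist(v, breaks = 256, plot = FALSE)
    pk0 <- h0$mids[which.max(h0$counts)]
    lo <- min(v)
    hi <- pk0 + 4 * max(pk0 - lo, diff(range(v)) / 256)
    vv <- v[v <= hi]
    if (stats::sd(vv) == 0) {
      # background is exactly constant (e.g. rendered scenes without noise)
      threshold <- vv[1] + 0
      return(structure(list(mu = vv[1], sigma = 0, threshold = threshold,
                            mask = array(as.numeric(image) < threshold,
                                         dim = dim(image))),
                       class = "background_model"))
    }
    h <- graphics::hist(vv, breaks = nbins, plot = FALSE)
    peak <- which.max(h$counts)
    left <- which(h$counts > 0 & seq_along(h$counts) <= peak)
    if (length(left) >= 4L) {
      # log counts of a Gaussian histogram are quadratic in the bin center;
      # weight by counts to approximate the Poisson likelihood
      x <- h$mids[left]; cts <- h$counts[left]
      fit <- stats::lm(log(cts) ~ x + I(x^2), weights = cts)
      b <- coef(fit)
      if (!is.finite(b[3]) || b[3] >= 0)
        abort("degenerate intensity histogram: left shoulder is not Gaussian")
      sigma <- sqrt(-1 / (2 * b[3]))
      mu <- -b[2] / (2 * b[3])
    } else {
      # too few left-shoulder bins (e.g. background piled in one bin):
      # half-normal moments of the pixels at or below the mode
      mu <- h$mids[peak]
      lo <- v[v <= mu]
      sigma <- if (length(lo) > 1L) sqrt(mean((mu - lo)^2)) else 0
    }
    if (!is.finite(mu) || !is.finite(sigma))
      abort("background fit failed on a degenerate histogram")
  }
  threshold <- mu + 3 * sigma
  structure(list(mu = mu, sigma = sigma, threshold = threshold,
                 mask = array(as.numeric(image) < threshold, dim = dim(image))),
            class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("<background_model> mu = %.4g, sigma = %.4g, threshold = %.4g\n",
              x$mu, x$sigma, x$threshold))
  invisible(x)
}

#' @export
glance.background_model <- function(x, ...) {
  tibble(mu = x$mu, sigma = x$sigma, threshold = x$threshold,
         frac_background = mean(x$mask))
}

subtract_bg_frames <- function(stack, bgmask) {
  # per-frame mean background (over the background mask) subtracted per frame
  nf <- dim(stack)[3]
  m2 <- if (length(dim(bgmask)) == 3L) bgmask[, , 1] else bgmask
  for (i in seq_len(nf)) {
    f <- stack[, , i]
    if (any(m2)) stack[, , i] <- f - mean(f[m2])
  }
  stack
}

#' G factor from an isotropic dye solution
#'
#' The G factor corrects the unequal throughput of the parallel and
#' perpendicular detection paths. On an isotropic solution the true
#' anisotropy is 0, so `G = mean(I_par) / mean(I_perp)` over
#' background-subtracted pixels makes the corrected anisotropy vanish.
#'
#' @param pair a [polar_pair] imaging an isotropic dye solution.
#' @param bg optional [estimate_background] model of the solution images; if
#'   `NULL` no background is subtracted (appropriate for full-field dye).
#' @return positive scalar G.
#' @export
g_factor_from_isotropic <- function(pair, bg = NULL) {
  stopifnot(inherits(pair, "polar_pair"))
  mpar <- mean(pair$parallel); mperp <- mean(pair$perpendicular)
  if (!is.null(bg)) { mpar <- mpar - bg$mu; mperp <- mperp - bg$mu }
  if (!is.finite(mperp) || mperp <= .Machine$double.eps * max(1, abs(mpar)))
    abort("perpendicular channel signal is zero or negative; cannot calibrate G")
  mpar / mperp
}

box3 <- matrix(1, 3, 3)

filter_box3 <- function(m) {
  # 3x3 box sum with edge replication
  EBImage::filter2(m, box3, boundary = "replicate")
}

#' Emission anisotropy map from a two-channel pair
#'
#' Computes per-pixel emission anisotropy
#' \deqn{r = (I_\parallel - I_\perp) / (I_\parallel + 2 I_\perp)}
#' after G-factor correction and per-frame, per-channel background
#' subtraction. With `prefilter = TRUE`, each pixel is replaced by the
#' intensity-weighted average anisotropy of its 3x3 neighborhood (weights =
#' per-pixel total intensity), which suppresses division-of-small-integer
#' artifacts. Pixels whose total intensity does not exceed `snr_gate` times
#' the background standard deviation are marked invalid rather than
#' propagating unstable ratios.
#'
#' @param pair a [polar_pair].
#' @param bg a `background_model` (from [estimate_background] of the total
#'   intensity); `NULL` means zero background and no intensity gate beyond
#'   positivity.
#' @param prefilter logical, apply the 3x3 intensity-weighted prefilter.
#' @param snr_gate multiple of the background sd a pixel's total intensity
#'   must exceed to be valid (default 4).
#' @return object of class `anisotropy_map`: list with `r` (array, NA on
#'   invalid pixels), `valid` (logical array), `total` (array of
#'   G-corrected total intensity) and `pixel_size`.
#' @export
anisotropy <- function(pair, bg = NULL, prefilter = TRUE, snr_gate = 4) {
  stopifnot(inherits(pair, "polar_pair"))
  par <- pair$parallel
  perp <- pair$perpendicular
  if (!is.null(bg)) {
    par <- subtract_bg_frames(par, bg$mask)
    perp <- subtract_bg_frames(perp, bg$mask)
  }
  perp <- pair$g_factor * perp
  total <- par + 2 * perp
  gate <- if (is.null(bg)) 0 else snr_gate * bg$sigma
  valid <- total > gate & total > 0
  r <- array(NA_real_, dim(total))
  r[valid] <- (par[valid] - perp[valid]) / total[valid]
  if (prefilter) {
    nf <- dim(total)[3]
    for (i in seq_len(nf)) {
      w <- total[, , i]
      w[!valid[, , i]] <- 0
      ri <- r[, , i]
      ri[!valid[, , i]] <- 0
      num <- filter_box3(ri * w)
      den <- filter_box3(w)
      out <- array(NA_real_, dim(w))
      ok <- valid[, , i] & den > 0
      out[ok] <- num[ok] / den[ok]
      r[, , i] <- out
    }
  }
  structure(list(r = r, valid = valid, total = total,
                 pixel_size = pair$pixel_size),
            class = "anisotropy_map")
}

#' @export
print.anisotropy_map <- function(x, ...) {
  cat(sprintf("<anisotropy_map> %d x %d px, %d frame(s), %.1f%% valid\n",
              dim(x$r)[1], dim(x$r)[2], dim(x$r)[3], 100 * mean(x$valid)))
  invisible(x)
}

#' Signal-to-noise ratio of a segmented region
#'
#' SNR is the mean intensity of the region (conventionally, of the
#' perpendicular channel) divided by the background standard deviation of
#' that channel. Regions with SNR below 5 are conventionally excluded;
#' SNR exactly 5 is kept.
#'
#' @param values intensities of the region's pixels.
#' @param bg a `background_model` for the same channel.
#' @return scalar SNR; `Inf` (with a warning) when the background sd is 0.
#' @export
region_snr <- function(values, bg) {
  if (length(values) == 0L) abort("empty region")
  if (bg$sigma == 0) {
    warn("background sd is zero; SNR is infinite")
    return(Inf)
  }
  mean(values) / bg$sigma
}

#' Calibrate a raw four-channel stack
#'
#' Divides each channel by its throughput factor (measured on an isotropic
#' dye solution), registers the three non-reference channels onto the
#' reference quadrant, and optionally subtracts a per-channel background
#' estimated from a small (default 4x4 px, about 0.28 um) square at the cell
#' center, which corrects residual background polarization and excitation
#' imbalance.
#'
#' @param quad a raw [quad_stack].
#' @param transforms list of 3 affine matrices (3x3, raster coordinates)
#'   mapping I45, I90, I135 onto I0, or `NULL` for identity.
#' @param cell_center `c(x, y)` pixel coordinates of the cell-center
#'   background ROI, or `NULL` to skip background subtraction.
#' @param roi_size side of the central background square in px.
#' @return calibrated `quad_stack`.
#' @export
quad_calibrate <- function(quad, transforms = NULL, cell_center = NULL,
                           roi_size = 4) {
  stopifnot(inherits(quad, "quad_stack"))
  if (is.null(quad$throughput)) abort("missing throughput calibration")
  ch_names <- c("I0", "I45", "I90", "I135")
  out <- quad
  for (k in seq_along(ch_names)) {
    out[[ch_names[k]]] <- quad[[ch_names[k]]] / quad$throughput[k]
  }
  if (!is.null(transforms)) {
    if (length(transforms) != 3L)
      abort("need 3 transforms (I45, I90, I135 onto the I0 reference)")
    for (k in 2:4) {
      tr <- transforms[[k - 1L]]
      if (is.null(tr)) next
      st <- out[[ch_names[k]]]
      for (i in seq_len(dim(st)[3]))
        st[, , i] <- apply_affine(st[, , i], tr)
      out[[ch_names[k]]] <- st
    }
  }
  if (!is.null(cell_center)) {
    half <- floor(roi_size / 2)
    cx <- round(cell_center[1]); cy <- round(cell_center[2])
    ny <- dim(out$I0)[1]; nx <- dim(out$I0)[2]
    ys <- max(1, cy - half + 1):min(ny, cy + half)
    xs <- max(1, cx - half + 1):min(nx, cx + half)
    for (k in ch_names) {
      st <- out[[k]]
      for (i in seq_len(dim(st)[3]))
        st[, , i] <- st[, , i] - mean(st[ys, xs, i])
      out[[k]] <- st
    }
  }
  out$throughput <- c(1, 1, 1, 1)
  out$calibrated <- TRUE
  out
}

#' Dipole orientation and polarization factor from four-channel intensities
#'
#' From background-corrected, throughput-normalized intensities analyzed at
#' 0, 45, 90 and 135 degrees:
#' \deqn{p = \sqrt{(I_0-I_{90})^2 + (I_{45}-I_{135})^2} /
#'       (0.5 (I_0+I_{45}+I_{90}+I_{135}))}
#' \deqn{\theta = \tfrac12 \,\mathrm{atan2}(I_{45}-I_{135},\; I_0-I_{90})}
#' with \eqn{\theta} folded to `[0, 180)`. The pair is the exact inverse of
#' the forward model \eqn{I(\alpha) = (I_{tot}/4)(1 + p\cos 2(\alpha-\theta))}.
#' Isotropic input (`p = 0`) leaves the orientation undefined; such entries
#' are flagged rather than given an arbitrary angle. Under noise `p` can
#' exceed 1; values are reported as-is with a flag, never silently clipped.
#'
#' @param I0,I45,I90,I135 numeric vectors (per pixel or per segment sums).
#' @return tibble with columns `theta_deg` (`[0,180)`, NA when isotropic),
#'   `p`, `total`, `isotropic` and `p_gt_1` flags.
#' @export
#' @examples
#' quad_polarization(3, 2, 1, 2)  # p = 0.5, theta = 0
quad_polarization <- function(I0, I45, I90, I135) {
  total <- I0 + I45 + I90 + I135
  if (any(!is.finite(total)) || any(total <= 0))
    abort("zero or non-finite total intensity")
  a <- I0 - I90
  b <- I45 - I135
  p <- sqrt(a^2 + b^2) / (0.5 * total)
  iso <- p <= .Machine$double.eps * 4
  theta <- fold180(0.5 * atan2(b, a) * 180 / pi)
  theta[iso] <- NA_real_
  tibble(theta_deg = theta, p = p, total = total,
         isotropic = iso, p_gt_1 = p > 1)
}

#' Anisotropy-versus-intensity diagnostic
#'
#' A linear trend of anisotropy with total intensity indicates homo-FRET
#' (energy transfer between like fluorophores depolarizes emission more at
#' higher label densities). This diagnostic reports the least-squares slope
#' and Pearson correlation of r against total intensity over valid pixels;
#' a slope near zero supports the absence of homo-FRET.
#'
#' @param amap an `anisotropy_map`.
#' @param mask optional logical array restricting the pixels used.
#' @return tibble with `slope` (anisotropy per intensity unit), `intercept`,
#'   `correlation` and `n_pixels`.
#' @export
anisotropy_intensity_diagnostic <- function(amap, mask = NULL) {
  stopifnot(inherits(amap, "anisotropy_map"))
  keep <- amap$valid
  if (!is.null(mask)) {
    if (length(dim(mask)) == 2L) mask <- array(mask, dim = dim(keep))
    keep <- keep & mask
  }
  r <- amap$r[keep]
  inten <- amap$total[keep]
  ok <- is.finite(r) & is.finite(inten)
  r <- r[ok]; inten <- inten[ok]
  if (length(r) < 100L)
    abort("fewer than 100 valid pixels for the anisotropy-intensity diagnostic")
  fit <- stats::lm(r ~ inten)
  tibble(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         correlation = stats::cor(r, inten), n_pixels = length(r))
}
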