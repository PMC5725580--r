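# Channel registration: bead-based affine estimation and automatic
# cross-correlation alignment.

#' Register one channel onto another
#'
#' `method = "auto"`: phase/intensity cross-correlation between the two
#' images, refined to sub-pixel precision by parabolic interpolation of the
#' correlation peak; returns a pure translation. `method = "beads"`: point
#' sources are detected in both images (local maxima with intensity-weighted
#' centroid refinement), matched by nearest neighbor after a coarse
#' cross-correlation shift, and a least-squares affine transform (capturing
#' translation, rotation and scale) is fitted to the matched pairs.
#'
#' @param moving,fixed numeric matrices.
#' @param method `"auto"` or `"beads"`.
#' @param min_beads minimum matched bead pairs (>= 3 needed for an affine).
#' @param peak_quantile intensity quantile above which bead candidates are
#'   detected.
#' @return list of class `channel_registration`: `transform` (3x3 affine
#'   mapping moving coordinates onto the fixed grid), `residual_rms` (px;
#'   bead-fit residual, or 0 for auto), `n_points`, `method`.
#' @export
register_channels <- function(moving, fixed, method = c("auto", "beads"),
                              min_beads = 3, peak_quantile = 0.99) {
  method <- match.arg(method)
  if (!identical(dim(moving), dim(fixed)))
    abort("moving and fixed images must share dimensions")
  if (method == "auto") {
    sh <- xcorr_shift(moving, fixed)
    tr <- translation_matrix(sh[1], sh[2])
    out <- list(transform = tr, residual_rms = 0, n_points = NA_integer_,
                method = "auto", peak = sh[3])
  } else {
    pm <- detect_beads(moving, peak_quantile)
    pf <- detect_beads(fixed, peak_quantile)
    if (nrow(pm) < min_beads || nrow(pf) < min_beads)
      abort(sprintf("fewer than %d bead candidates detected", min_beads))
    sh <- xcorr_shift(moving, fixed)
    shifted <- cbind(pm$x + sh[1], pm$y + sh[2])
    # nearest-neighbor matching within a tolerance
    match_idx <- apply(shifted, 1, function(p) {
      d2 <- (pf$x - p[1])^2 + (pf$y - p[2])^2
      i <- which.min(d2)
      if (d2[i] <= 9) i else NA_integer_
    })
    ok <- !is.na(match_idx)
    if (sum(ok) < min_beads)
      abort(sprintf("fewer than %d matched bead pairs", min_beads))
    src <- cbind(pm$x[ok], pm$y[ok])
    dst <- cbind(pf$x[match_idx[ok]], pf$y[match_idx[ok]])
    X <- cbind(src, 1)
    bx <- stats::lm.fit(X, dst[, 1])$coefficients
    by <- stats::lm.fit(X, dst[, 2])$coefficients
    tr <- rbind(bx, by, c(0, 0, 1))
    pred <- X %*% t(tr[1:2, ])
    rms <- sqrt(mean(rowSums((pred - dst)^2)))
    out <- list(transform = unname(tr), residual_rms = rms,
                n_points = sum(ok), method = "beads")
  }
  class(out) <- "channel_registration"
  out
}

#' @export
print.channel_registration <- function(x, ...) {
  cat(sprintf("<channel_registration> %s: dx = %.3f, dy = %.3f, residual = %.3g px%s\n",
              x$method, x$transform[1, 3], x$transform[2, 3], x$residual_rms,
              if (is.na(x$n_points)) "" else sprintf(" (%d beads)", x$n_points)))
  invisible(x)
}

# integer + parabolic sub-pixel shift (dx, dy) maximizing correlation of
# moving shifted onto fixed; returns c(dx, dy, peak_value)
xcorr_shift <- function(moving, fixed) {
  a <- moving - mean(moving); b <- fixed - mean(fixed)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    abort("flat image: cannot cross-correlate")
  Fa <- stats::fft(a); Fb <- stats::fft(b)
  cc <- Re(stats::fft(Fb * Conj(Fa), inverse = TRUE))
  ny <- nrow(cc); nx <- ncol(cc)
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  wrap <- function(i, n) ifelse(i - 1 > n / 2, i - 1 - n, i - 1)
  dy <- wrap(pk[1], ny); dx <- wrap(pk[2], nx)
  sub <- function(m, i, j) m[((i - 1) %% ny) + 1, ((j - 1) %% nx) + 1]
  refine <- function(cm, c0, cp) {
    den <- cm - 2 * c0 + cp
    if (den < 0) 0.5 * (cm - cp) / den else 0
  }
  ddx <- refine(sub(cc, pk[1], pk[2] - 1), cc[pk[1], pk[2]], sub(cc, pk[1], pk[2] + 1))
  ddy <- refine(sub(cc, pk[1] - 1, pk[2]), cc[pk[1], pk[2]], sub(cc, pk[1] + 1, pk[2]))
  c(dx + ddx, dy + ddy, max(cc) / (stats::sd(a) * stats::sd(b) * length(a)))
}

detect_beads <- function(img, peak_quantile = 0.99, win = 2L) {
  thr <- stats::quantile(img, peak_quantile)
  mx <- EBImage::filter2(img, matrix(1, 2 * win + 1, 2 * win + 1) /
                           (2 * win + 1)^2, boundary = "replicate")
  cand <- which(img >= thr, arr.ind = TRUE)
  ny <- nrow(img); nx <- ncol(img)
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    ys <- max(1, i - win):min(ny, i + win)
    xs <- max(1, j - win):min(nx, j + win)
    keep[k] <- img[i, j] == max(img[ys, xs])
  }
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0L) return(tibble(x = double(), y = double()))
  pts <- t(apply(cand, 1, function(p) {
    i <- p[1]; j <- p[2]
    ys <- max(1, i - win):min(ny, i + win)
    xs <- max(1, j - win):min(nx, j + win)
    w <- img[ys, xs]
    c(sum(rep(xs, each = length(ys)) * w) / sum(w),
      sum(rep(ys, length(xs)) * w) / sum(w))
  }))
  d <- tibble(x = pts[, 1], y = pts[, 2])
  # deduplicate near-identical centroids
  d[!duplicated(round(cbind(d$x, d$y) / 2)), ]
}
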