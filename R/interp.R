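# Raster resampling primitives shared by registration, calibration,
# flow warping and kymograph extraction.

#' Bilinear sampling of a raster at arbitrary coordinates
#'
#' @param m numeric matrix (rows = y, cols = x).
#' @param x,y numeric vectors of sample coordinates (1-based, col/row).
#'   Coordinates are clamped to the image border.
#' @return numeric vector of sampled values.
#' @export
bilinear_sample <- function(m, x, y) {
  ny <- nrow(m); nx <- ncol(m)
  x <- pmin(pmax(x, 1), nx)
  y <- pmin(pmax(y, 1), ny)
  x0 <- pmin(floor(x), nx - 1L); y0 <- pmin(floor(y), ny - 1L)
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(y0, x0); i01 <- cbind(y0, x0 + 1)
  i10 <- cbind(y0 + 1, x0); i11 <- cbind(y0 + 1, x0 + 1)
  m[i00] * (1 - fx) * (1 - fy) + m[i01] * fx * (1 - fy) +
    m[i10] * (1 - fx) * fy + m[i11] * fx * fy
}

#' Resample an image under an affine transform
#'
#' `transform` maps moving-image coordinates onto the fixed grid:
#' `(x', y', 1)^T = A (x, y, 1)^T`. The output raster lives on the fixed
#' grid; each output pixel is bilinearly sampled from the moving image at
#' the inverse-mapped location.
#'
#' @param m numeric matrix (the moving image).
#' @param transform 3x3 affine matrix.
#' @return matrix of the same dimensions.
#' @export
apply_affine <- function(m, transform) {
  ny <- nrow(m); nx <- ncol(m)
  Ainv <- solve(transform)
  g <- expand.grid(x = seq_len(nx), y = seq_len(ny))
  src <- Ainv %*% rbind(g$x, g$y, 1)
  matrix(bilinear_sample(m, src[1, ], src[2, ]), ny, nx, byrow = TRUE)
}

#' Affine matrix for a pure translation
#' @param dx,dy translation in px (x rightward, y downward).
#' @return 3x3 matrix.
#' @export
translation_matrix <- function(dx, dy) {
  matrix(c(1, 0, dx, 0, 1, dy, 0, 0, 1), 3, 3, byrow = TRUE)
}

# Exact periodic sub-pixel translation of a band-limited raster via the
# Fourier shift theorem. Positive (dx, dy) moves the pattern rightward /
# downward.
fourier_shift <- function(m, dx, dy) {
  ny <- nrow(m); nx <- ncol(m)
  ky <- c(0:floor(ny / 2), -(ceiling(ny / 2) - 1):-1)[1:ny]
  kx <- c(0:floor(nx / 2), -(ceiling(nx / 2) - 1):-1)[1:nx]
  phase <- exp(-2i * pi * (outer(ky, rep(1, nx)) * dy / ny +
                           outer(rep(1, ny), kx) * dx / nx))
  Re(stats::fft(stats::fft(m) * phase, inverse = TRUE)) / (ny * nx)
}
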