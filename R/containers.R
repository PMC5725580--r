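# Light S3 containers for image data. Rasters are numeric arrays with
# dim = c(ny, nx, n_frames); single frames are promoted. Tabular results
# elsewhere in the package are tibbles.

as_stack <- function(x, what = "image") {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  if (!is.array(x) || length(dim(x)) != 3L)
    abort(sprintf("%s must be a matrix or a ny x nx x n_frames array", what))
  storage.mode(x) <- "double"
  x
}

#' Two-channel polarized image pair (parallel / perpendicular)
#'
#' Container for registered emission-anisotropy TIRF data: a parallel and a
#' perpendicular detection channel sharing one pixel grid, plus the G factor
#' correcting their relative detection throughput.
#'
#' @param parallel,perpendicular matrices or `ny x nx x n_frames` arrays of
#'   intensities on a common grid.
#' @param g_factor positive scalar throughput correction; the corrected
#'   perpendicular channel is `g_factor * perpendicular`.
#' @param pixel_size pixel size in nm.
#' @return object of class `polar_pair`.
#' @export
polar_pair <- function(parallel, perpendicular, g_factor = 1,
                       pixel_size = 109) {
  parallel <- as_stack(parallel, "parallel")
  perpendicular <- as_stack(perpendicular, "perpendicular")
  if (!identical(dim(parallel), dim(perpendicular)))
    abort("parallel and perpendicular channels must share dimensions")
  if (!is.numeric(g_factor) || length(g_factor) != 1L || g_factor <= 0)
    abort("g_factor must be a positive scalar")
  if (pixel_size <= 0) abort("pixel_size must be positive (nm)")
  structure(list(parallel = parallel, perpendicular = perpendicular,
                 g_factor = g_factor, pixel_size = pixel_size),
            class = "polar_pair")
}

#' @export
print.polar_pair <- function(x, ...) {
  d <- dim(x$parallel)
  cat(sprintf("<polar_pair> %d x %d px, %d frame(s), G = %.4g, %.4g nm/px\n",
              d[1], d[2], d[3], x$g_factor, x$pixel_size))
  invisible(x)
}

#' Four-channel polarization-resolved image stack
#'
#' Container for instantaneous four-angle polarization data: emission
#' analyzed at 0, 45, 90 and 135 degrees on a common pixel grid, with the
#' per-channel throughput factors measured on an isotropic dye solution.
#'
#' @param I0,I45,I90,I135 matrices or `ny x nx x n_frames` arrays.
#' @param throughput positive numeric length-4 vector; channels are divided
#'   by these factors during calibration.
#' @param pixel_size pixel size in nm.
#' @param calibrated logical, whether throughput/background correction has
#'   been applied already.
#' @return object of class `quad_stack`.
#' @export
quad_stack <- function(I0, I45, I90, I135, throughput = c(1, 1, 1, 1),
                       pixel_size = 109, calibrated = FALSE) {
  ch <- list(I0 = as_stack(I0, "I0"), I45 = as_stack(I45, "I45"),
             I90 = as_stack(I90, "I90"), I135 = as_stack(I135, "I135"))
  dims <- lapply(ch, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    abort("all four channels must share dimensions")
  if (length(throughput) != 4L || any(!is.finite(throughput)) ||
      any(throughput <= 0))
    abort("throughput must be 4 positive factors")
  structure(c(ch, list(throughput = as.numeric(throughput),
                       pixel_size = pixel_size,
                       calibrated = isTRUE(calibrated))),
            class = "quad_stack")
}

#' @export
print.quad_stack <- function(x, ...) {
  d <- dim(x$I0)
  cat(sprintf("<quad_stack> %d x %d px, %d frame(s), %s, %.4g nm/px\n",
              d[1], d[2], d[3],
              if (x$calibrated) "calibrated" else "raw", x$pixel_size))
  invisible(x)
}

n_frames <- function(x) dim(x[[1]])[3]

frame_of <- function(stack, i) stack[, , i, drop = TRUE]

#' Total fluorescence intensity of a stack
#'
#' For a `polar_pair` this is the anisotropy-weighted total
#' `I_par + 2 * G * I_perp` (the denominator of the anisotropy); for a
#' `quad_stack` it is the sum of the four channels.
#'
#' @param x a `polar_pair` or `quad_stack`.
#' @return array with the same dimensions as one channel.
#' @export
total_intensity <- function(x) {
  if (inherits(x, "polar_pair")) {
    x$parallel + 2 * x$g_factor * x$perpendicular
  } else if (inherits(x, "quad_stack")) {
    x$I0 + x$I45 + x$I90 + x$I135
  } else {
    abort("total_intensity() needs a polar_pair or quad_stack")
  }
}
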