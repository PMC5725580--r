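# Angle conventions used everywhere in the package.
#
# Rasters are plain R matrices with dim = c(ny, nx): row index = y, increasing
# downward as displayed; column index = x, increasing rightward. Angles are
# measured counter-clockwise in the conventional display orientation (y up),
# so a vector (dx, dy) in raster coordinates has display angle atan2(-dy, dx).
# Transition dipoles have twofold (dyad) symmetry, so orientations live on
# [0, 180) degrees; a single folding helper enforces this everywhere.

#' Fold an angle into the dipole orientation range [0, 180) degrees
#'
#' Transition dipoles are axes, not arrows: an orientation and its 180-degree
#' rotation are physically identical, so all dipole and membrane-axis angles
#' in this package are reported modulo 180 degrees.
#'
#' @param deg numeric vector of angles in degrees.
#' @return numeric vector in `[0, 180)`.
#' @export
#' @examples
#' fold180(c(-10, 190, 360.5))
fold180 <- function(deg) {
  ((deg %% 180) + 180) %% 180
}

#' Counter-clockwise display angle of a raster-coordinate vector
#'
#' Converts a vector given in raster coordinates (`dx` rightward, `dy`
#' downward) into the counter-clockwise angle convention (y up) used for all
#' orientations, folded to `[0, 180)`.
#'
#' @param dx,dy numeric vectors, vector components in raster coordinates.
#' @return angles in degrees in `[0, 180)`.
#' @export
raster_angle <- function(dx, dy) {
  fold180(atan2(-dy, dx) * 180 / pi)
}

#' Circular distance between two orientations (period 180 degrees)
#'
#' @param a,b angles in degrees (any range; folded internally).
#' @return non-negative distance in degrees, at most 90.
#' @export
#' @examples
#' circ_dist180(2, 178)  # 4, not 176
circ_dist180 <- function(a, b) {
  d <- abs(fold180(a) - fold180(b))
  pmin(d, 180 - d)
}

#' Weighted circular mean and spread of orientations (period 180 degrees)
#'
#' Angles are doubled to map the 180-degree-periodic orientation circle onto
#' the full circle, the weighted resultant is computed, and the mean and a
#' wrapped-normal standard deviation are mapped back. This is the moment
#' estimator for a wrapped normal on the orientation circle.
#'
#' @param deg angles in degrees.
#' @param w non-negative weights (default equal).
#' @return list with `mean` (degrees in `[0,180)`), `sd` (degrees), and
#'   `resultant` (mean resultant length on the doubled circle, in `[0,1]`).
#' @export
circular_mean180 <- function(deg, w = NULL) {
  if (length(deg) == 0L) abort("no angles supplied")
  if (is.null(w)) w <- rep(1, length(deg))
  if (any(w < 0)) abort("weights must be non-negative")
  sw <- sum(w)
  if (sw <= 0) abort("all weights are zero")
  a2 <- 2 * fold180(deg) * pi / 180
  cbar <- sum(w * cos(a2)) / sw
  sbar <- sum(w * sin(a2)) / sw
  rbar <- sqrt(cbar^2 + sbar^2)
  mean_deg <- fold180(atan2(sbar, cbar) * 180 / (2 * pi))
  sd_deg <- if (rbar <= .Machine$double.eps) Inf else
    sqrt(-2 * log(min(rbar, 1))) * 180 / (2 * pi)
  list(mean = mean_deg, sd = sd_deg, resultant = rbar)
}
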