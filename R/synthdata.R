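# Synthetic scenes with ground-truth sidecars. The generators emulate the
# study conditions: cells with protruding leading edges, per-pixel dipole
# orientation fields tied to the local membrane normal with a set amplitude
# of angular dependence, Gaussian background plus shot-like noise, and
# texture movies translating at a known velocity. Every generated stack
# carries a ground-truth sidecar of identical spatial dimensions, and every
# generator is bit-for-bit seed-reproducible.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Specification of a synthetic polarization scene
#'
#' Collects the generation parameters for [make_ea_scene] and
#' [make_quad_scene]: image geometry, cell shape, the angular-dependence
#' parameters (baseline `C`, absolute amplitude `A`, dipole angle `theta_d`
#' from the membrane normal), total in-cell intensity, background and noise.
#'
#' @param height,width image size, px.
#' @param pixel_size nm per px (default 109).
#' @param n_frames number of frames.
#' @param cell_shape `"disk"` or `"blob_protrusion"` (a disk growing a
#'   half-disk bump over the frames, giving protrusion detection a positive
#'   signal).
#' @param cell_radius cell radius, px.
#' @param baseline_C baseline anisotropy `C`.
#' @param amplitude_A absolute amplitude `A` of the angular dependence
#'   (anisotropy units, >= 0).
#' @param theta_d dipole angle from the membrane normal, degrees.
#' @param total_intensity in-cell total intensity (constant, set well above
#'   the SNR gate so noiseless scenes exclude no pixels).
#' @param background_mean,background_sd camera background parameters.
#' @param noise_model `"none"`, `"gaussian"`, or `"poisson"`. With
#'   `"none"` the scene is a deterministic function of the other fields.
#' @param p polarization factor for four-channel scenes (`[0, 1]`).
#' @param p_body polarization factor of the cell body (pixels deeper than
#'   `edge_width`); defaults to `p` (uniform).
#' @param theta_sd per-pixel wrapped-normal jitter of `theta_d`, degrees.
#' @param edge_width depth of the edge band for `p`/`p_body` split, px.
#' @param orientation_bin bin width (degrees) to which the orientation field
#'   is quantized before the angular dependence is applied in
#'   [make_ea_scene]; matching the analysis binning makes the ideal-image
#'   pipeline exactly invertible. 0 disables quantization.
#' @param bump_radius range `c(from, to)` of the protrusion bump radius
#'   grown linearly over the frames, px.
#' @param seed RNG seed for the stochastic parts.
#' @return list of class `scene_spec`.
#' @export
scene_spec <- function(height = 192, width = 192, pixel_size = 109,
                       n_frames = 1, cell_shape = c("disk", "blob_protrusion"),
                       cell_radius = 60, baseline_C = 0.1, amplitude_A = 0.05,
                       theta_d = 90, total_intensity = 1000,
                       background_mean = 0, background_sd = 0,
                       noise_model = c("none", "gaussian", "poisson"),
                       p = 0.5, p_body = NULL, theta_sd = 0,
                       edge_width = 10, bump_radius = c(12, 40),
                       orientation_bin = 10, seed = 1L) {
  cell_shape <- match.arg(cell_shape)
  noise_model <- match.arg(noise_model)
  if (amplitude_A < 0) abort("amplitude_A must be >= 0")
  if (background_sd < 0) abort("background_sd must be >= 0")
  if (pixel_size <= 0) abort("pixel_size must be > 0")
  if (p < 0 || p > 1) abort("p must lie in [0, 1]")
  if (!is.null(p_body) && (p_body < 0 || p_body > 1))
    abort("p_body must lie in [0, 1]")
  structure(list(height = height, width = width, pixel_size = pixel_size,
                 n_frames = n_frames, cell_shape = cell_shape,
                 cell_radius = cell_radius, baseline_C = baseline_C,
                 amplitude_A = amplitude_A, theta_d = theta_d,
                 total_intensity = total_intensity,
                 background_mean = background_mean,
                 background_sd = background_sd, noise_model = noise_model,
                 p = p, p_body = p_body, theta_sd = theta_sd,
                 edge_width = edge_width, bump_radius = bump_radius,
                 orientation_bin = orientation_bin, seed = as.integer(seed)),
            class = "scene_spec")
}

disk_mask <- function(ny, nx, cx, cy, radius) {
  X <- matrix(rep(seq_len(nx), each = ny), ny, nx)
  Y <- matrix(rep(seq_len(ny), nx), ny, nx)
  (X - cx)^2 + (Y - cy)^2 <= radius^2
}

scene_masks <- function(spec) {
  ny <- spec$height; nx <- spec$width
  cx <- nx / 2; cy <- ny / 2
  base <- disk_mask(ny, nx, cx, cy, spec$cell_radius)
  masks <- array(FALSE, c(ny, nx, spec$n_frames))
  for (i in seq_len(spec$n_frames)) {
    m <- base
    if (spec$cell_shape == "blob_protrusion") {
      frac <- if (spec$n_frames > 1) (i - 1) / (spec$n_frames - 1) else 1
      rb <- spec$bump_radius[1] + frac * diff(spec$bump_radius)
      m <- m | disk_mask(ny, nx, cx + spec$cell_radius, cy, rb)
    }
    masks[, , i] <- m
  }
  masks
}

add_noise <- function(stack, spec) {
  stack <- stack + spec$background_mean
  if (spec$noise_model == "gaussian" && spec$background_sd > 0) {
    stack <- stack + array(rnorm(length(stack), 0, spec$background_sd),
                           dim(stack))
  } else if (spec$noise_model == "poisson") {
    stack <- array(rpois(length(stack), pmax(stack, 0)) * 1.0, dim(stack)) +
      if (spec$background_sd > 0)
        array(rnorm(length(stack), 0, spec$background_sd), dim(stack)) else 0
  }
  stack
}

#' Render a two-channel (parallel/perpendicular) scene with known truth
#'
#' The per-pixel true anisotropy is
#' \deqn{r(\gamma) = C + A \cos^2(\gamma - \theta_d)}
#' where `gamma` is the pixel's orientation relative to the local membrane
#' normal computed by [orientation_map] on the same cell mask the analysis
#' will see, so generation and analysis share one geometry definition. The
#' channel pair is rendered by inverting the anisotropy identity at a
#' constant in-cell total intensity: `I_par = I_tot (1 + 2 r) / 3`,
#' `I_perp = I_tot (1 - r) / 3`. Background and noise are added per the
#' spec. Pixels on the medial-axis ridge, where the orientation is
#' undefined, are rendered at the mean anisotropy `C + A/2` and carry NA in
#' the ground truth. The orientation field is quantized to
#' `spec$orientation_bin` degrees before the cosine is applied — the same
#' quantization the fitting step uses — so the noiseless ideal-image
#' pipeline is exactly invertible (fits with R^2 = 1 and the generating
#' amplitude and phase).
#'
#' @param spec a [scene_spec]. `baseline_C + amplitude_A` must stay inside
#'   the representable anisotropy range `[-0.5, 1]`.
#' @return list of class `ea_scene`: `pair` (a [polar_pair]) and `truth`
#'   (list of `orientation`, `r`, `mask` stacks matching the pair's
#'   dimensions, plus the spec).
#' @export
make_ea_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  if (spec$baseline_C + spec$amplitude_A > 1 || spec$baseline_C < -0.5)
    abort("C + A outside the representable anisotropy range [-0.5, 1]")
  masks <- scene_masks(spec)
  dims <- dim(masks)
  ori <- array(NA_real_, dims)
  r_true <- array(NA_real_, dims)
  par <- array(0, dims); perp <- array(0, dims)
  for (i in seq_len(dims[3])) {
    m <- masks[, , i]
    g <- orientation_map(m)
    if (spec$orientation_bin > 0)
      g <- fold180(round(g / spec$orientation_bin) * spec$orientation_bin)
    r <- spec$baseline_C +
      spec$amplitude_A * cos((g - spec$theta_d) * pi / 180)^2
    r_render <- r
    r_render[m & is.na(r)] <- spec$baseline_C + spec$amplitude_A / 2
    itot <- ifelse(m, spec$total_intensity, 0)
    par[, , i] <- itot * (1 + 2 * ifelse(is.na(r_render), 0, r_render)) / 3
    perp[, , i] <- itot * (1 - ifelse(is.na(r_render), 0, r_render)) / 3
    ori[, , i] <- g
    r_true[, , i] <- r
  }
  with_seed(spec$seed, {
    par <- add_noise(par, spec)
    perp <- add_noise(perp, spec)
  })
  structure(list(pair = polar_pair(par, perp, g_factor = 1,
                                   pixel_size = spec$pixel_size),
                 truth = list(orientation = ori, r = r_true, mask = masks,
                              spec = spec)),
            class = "ea_scene")
}

#' Render a four-channel polarization-resolved scene with known truth
#'
#' Per-pixel channel intensities follow the forward model
#' \deqn{I(\alpha) = (I_{tot}/4)(1 + p\cos 2(\alpha - \theta)),\quad
#'       \alpha \in \{0, 45, 90, 135\}^\circ}
#' with the dipole orientation `theta` set at the offset `theta_d` from the
#' local membrane-normal axis (the [orientation_map] of the cell mask),
#' optionally jittered per pixel by a wrapped normal of sd `theta_sd`.
#' When `p_body` is given, pixels deeper than `edge_width` px from the
#' boundary carry `p_body` instead of `p`, so leading-edge order against a
#' disordered body is testable.
#'
#' @param spec a [scene_spec].
#' @return list of class `quad_scene`: `quad` (a [quad_stack]) and `truth`
#'   (`theta`, `p`, `mask` stacks plus the spec).
#' @export
make_quad_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  masks <- scene_masks(spec)
  dims <- dim(masks)
  ch <- lapply(1:4, function(k) array(0, dims))
  alphas <- c(0, 45, 90, 135)
  th_true <- array(NA_real_, dims)
  p_true <- array(NA_real_, dims)
  with_seed(spec$seed, {
    for (i in seq_len(dims[3])) {
      m <- masks[, , i]
      g <- orientation_map(m)
      theta <- fold180(g + spec$theta_d)
      if (spec$theta_sd > 0)
        theta <- fold180(theta + array(rnorm(length(theta), 0, spec$theta_sd),
                                       dim(theta)))
      pmap_ <- ifelse(m, spec$p, 0)
      if (!is.null(spec$p_body)) {
        er <- EBImage::erode(m * 1, disc_brush(spec$edge_width)) > 0
        pmap_[er] <- spec$p_body
      }
      pmap_[m & is.na(theta)] <- 0
      th0 <- ifelse(is.na(theta), 0, theta)
      itot <- ifelse(m, spec$total_intensity, 0)
      for (k in 1:4) {
        ch[[k]][, , i] <- (itot / 4) *
          (1 + pmap_ * cos(2 * (alphas[k] - th0) * pi / 180))
      }
      th_true[, , i] <- ifelse(pmap_ > 0, theta, NA_real_)
      p_true[, , i] <- ifelse(m, pmap_, NA_real_)
    }
    for (k in 1:4) ch[[k]] <- add_noise(ch[[k]], spec)
  })
  structure(list(quad = quad_stack(ch[[1]], ch[[2]], ch[[3]], ch[[4]],
                                   pixel_size = spec$pixel_size,
                                   calibrated = TRUE),
                 truth = list(theta = th_true, p = p_true, mask = masks,
                              spec = spec)),
            class = "quad_scene")
}

#' Rigidly translating band-limited texture movie with known flow
#'
#' Generates a smooth random texture (seeded white noise blurred with a
#' Gaussian) and translates it rigidly at the requested velocity using exact
#' periodic Fourier shifts, so brightness constancy holds to machine
#' precision. The ground truth stores the per-frame displacement vector in
#' raster coordinates.
#'
#' @param spec a [scene_spec] (image size, pixel size, frame count, seed,
#'   background/noise fields are honored).
#' @param velocity speed in nm/s.
#' @param direction direction of motion, degrees counter-clockwise in
#'   display convention (0 = rightward, 90 = up-screen).
#' @param frame_interval s between frames.
#' @param texture_sigma Gaussian blur radius of the texture, px.
#' @param contrast texture sd in intensity units.
#' @return list of class `flow_scene`: `stack` (array), `truth` (list with
#'   `vx`, `vy` px/frame, full fields of same spatial size), `pixel_size`,
#'   `frame_interval`.
#' @export
make_flow_movie <- function(spec, velocity, direction = 180,
                            frame_interval = 1, texture_sigma = 3,
                            contrast = 100) {
  stopifnot(inherits(spec, "scene_spec"))
  shift <- velocity * frame_interval / spec$pixel_size   # px/frame
  vx <- shift * cos(direction * pi / 180)
  vy <- -shift * sin(direction * pi / 180)
  ny <- spec$height; nx <- spec$width
  tex <- with_seed(spec$seed, matrix(rnorm(ny * nx), ny, nx))
  tex <- EBImage::gblur(tex, sigma = texture_sigma)
  tex <- contrast * tex / stats::sd(tex) + 10 * contrast
  stack <- array(0, c(ny, nx, spec$n_frames))
  for (i in seq_len(spec$n_frames))
    stack[, , i] <- fourier_shift(tex, (i - 1) * vx, (i - 1) * vy)
  with_seed(spec$seed + 1L, stack <- add_noise(stack, spec))
  structure(list(stack = stack,
                 truth = list(vx = vx, vy = vy,
                              vx_field = matrix(vx, ny, nx),
                              vy_field = matrix(vy, ny, nx)),
                 pixel_size = spec$pixel_size,
                 frame_interval = frame_interval),
            class = "flow_scene")
}

#' Synthetic radial inflow field on a disk cell
#'
#' Builds a `flow_field` object directly (no movie): every in-cell pixel
#' moves toward the disk center at `speed_px` px/frame, emulating retrograde
#' flow normal to the boundary everywhere. Used to test the
#' angle-versus-tangent chain, whose expected mean is 90 degrees.
#'
#' @param ny,nx image size; @param cx,cy disk center; @param radius px.
#' @param speed_px inward speed, px/frame.
#' @param pixel_size nm; @param frame_interval s.
#' @return a `flow_field` (see [lucas_kanade_flow]) with one frame pair.
#' @export
radial_inflow_field <- function(ny = 192, nx = 192, cx = nx / 2, cy = ny / 2,
                                radius = 60, speed_px = 1,
                                pixel_size = 109, frame_interval = 1) {
  X <- matrix(rep(seq_len(nx), each = ny), ny, nx)
  Y <- matrix(rep(seq_len(ny), nx), ny, nx)
  dx <- cx - X; dy <- cy - Y
  d <- sqrt(dx^2 + dy^2)
  m <- d <= radius & d > 1
  vx <- array(0, c(ny, nx, 1)); vy <- array(0, c(ny, nx, 1))
  vx[, , 1][m] <- speed_px * dx[m] / d[m]
  vy[, , 1][m] <- speed_px * dy[m] / d[m]
  valid <- array(FALSE, c(ny, nx, 1)); valid[, , 1] <- m
  structure(list(vx = vx, vy = vy, valid = valid,
                 pixel_size = pixel_size, frame_interval = frame_interval,
                 params = list(synthetic = "radial_inflow")),
            class = "flow_field")
}

#' Synthetic dipole ensemble about a mean direction
#'
#' Draws `n` unit vectors around `mean_direction` with dispersion decreasing
#' in `concentration` (Gaussian perturbation of sd `1/sqrt(concentration)`
#' per axis, renormalized; `concentration = 0` gives the uniform sphere).
#' Each member receives a pseudo-energy increasing with its angular
#' deviation from the mean plus seeded noise, so the lowest-energy-fraction
#' selection rule is exercisable: selecting low-energy members tightens the
#' ensemble.
#'
#' @param mean_direction length-3 vector (normalized internally).
#' @param concentration >= 0, dimensionless.
#' @param n number of members.
#' @param seed RNG seed.
#' @return a [dipole_ensemble].
#' @export
make_ensemble <- function(mean_direction = c(0, 1, 0), concentration = 50,
                          n = 200, seed = 1L) {
  if (n < 1L) abort("n must be >= 1")
  if (concentration < 0) abort("concentration must be >= 0")
  mu <- mean_direction / sqrt(sum(mean_direction^2))
  with_seed(seed, {
    if (concentration == 0) {
      v <- matrix(rnorm(3 * n), n, 3)
    } else {
      sigma <- 1 / sqrt(concentration)
      v <- matrix(rep(mu, each = n), n, 3) + sigma * matrix(rnorm(3 * n), n, 3)
    }
    v <- v / sqrt(rowSums(v^2))
    dev <- acos(pmin(1, abs(v %*% mu))) * 180 / pi
    energy <- as.numeric(dev) + rnorm(n, 0, 2)
  })
  dipole_ensemble(v, energy)
}
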