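test_that("orientation map matches the radial azimuth on a disk", {
  m <- test_disk(121, 121, 61, 61, 45)
  o <- orientation_map(m)
  expect_equal(o[61, 95], 0)    # due east
  expect_equal(o[30, 61], 90)   # due north
  # analytic oracle: folded azimuth of the outward radial direction,
  # away from the center singularity
  idx <- which(is.finite(o), arr.ind = TRUE)
  dx <- idx[, 2] - 61; dy <- idx[, 1] - 61
  d <- sqrt(dx^2 + dy^2)
  keep <- d > 8 & d < 42
  truth <- raster_angle(dx[keep], dy[keep])
  dev <- circ_dist180(o[idx[keep, , drop = FALSE]], truth)
  expect_lt(max(dev), 3)
  expect_error(orientation_map(matrix(FALSE, 10, 10)), "empty")
})

test_that("orientation map is constant per side of a square cell", {
  m <- matrix(FALSE, 140, 140)
  m[30:110, 30:110] <- TRUE
  o <- orientation_map(m)
  # side interiors (away from the diagonal ridge): east side points 0,
  # north side points 90
  east <- na.omit(as.vector(o[68:72, 100:105]))
  north <- na.omit(as.vector(o[35:40, 68:72]))
  expect_lt(max(circ_dist180(east, 0)), 0.01)
  expect_lt(max(circ_dist180(north, 90)), 0.01)
})

test_that("cos^2 fit recovers exact parameters from bin-center samples", {
  g <- rep(seq(0, 165, by = 15), each = 20)
  r <- 0.1 + 0.05 * cos((g - 30) * pi / 180)^2
  fit <- cos2_fit(r, g, bin_width = 15)
  expect_equal(fit$C, 0.1, tolerance = 1e-12)
  expect_equal(fit$A, 0.05, tolerance = 1e-12)
  expect_equal(fit$theta_d, 30, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("cos^2 fit flags degenerate and low-coverage input", {
  g <- rep(seq(0, 165, by = 15), each = 5)
  fit <- cos2_fit(rep(0.2, length(g)), g)
  expect_equal(fit$status, "degenerate")
  expect_true(is.na(fit$theta_d))
  expect_error(cos2_fit(runif(30), rep(c(0, 10, 20), 10)), "coverage")
})

test_that("noiseless scenes round-trip through the full fitting chain", {
  for (th in c(0, 45, 137)) {
    sc <- make_ea_scene(scene_spec(theta_d = th, amplitude_A = 0.05))
    am <- anisotropy(sc$pair, bg = NULL, prefilter = FALSE)
    ori <- orientation_map(sc$truth$mask[, , 1])
    sel <- sc$truth$mask[, , 1] & am$valid[, , 1] & is.finite(ori)
    fit <- cos2_fit(am$r[, , 1][sel], ori[sel], bin_width = 10)
    expect_lt(abs(fit$A - 0.05), 1e-3)
    expect_lt(circ_dist180(fit$theta_d, th), 0.5)
    expect_gte(fit$r_squared, 0.999)
  }
})

test_that("pixel-mode fit agrees with binned-mode on exact data", {
  g <- rep(seq(0, 170, by = 10), each = 30)
  r <- 0.12 + 0.06 * cos((g - 75) * pi / 180)^2
  fb <- cos2_fit(r, g, bin_width = 10, mode = "binned")
  fp <- cos2_fit(r, g, bin_width = 10, mode = "pixels")
  expect_equal(fb$A, fp$A, tolerance = 1e-10)
  expect_equal(fb$theta_d, fp$theta_d, tolerance = 1e-8)
})

test_that("Fourier amplitude equals half the cos^2 amplitude", {
  g <- runif(5000, 0, 180)
  r <- 0.1 + 0.05 * cos((g - 60) * pi / 180)^2
  fa <- fourier_amplitude(r, g)
  expect_equal(fa$amplitude, 0.05 / 2, tolerance = 0.01)
  expect_lt(circ_dist180(fa$phase_deg, 60), 2)
  # constant signal: zero amplitude
  fa0 <- fourier_amplitude(rep(0.2, 1000), runif(1000, 0, 180))
  expect_lt(fa0$amplitude, 1e-12)
})

test_that("Fourier and cos^2 amplitudes agree on noiseless fixtures", {
  sc <- make_ea_scene(scene_spec(theta_d = 120))
  am <- anisotropy(sc$pair, bg = NULL, prefilter = FALSE)
  ori <- orientation_map(sc$truth$mask[, , 1])
  sel <- sc$truth$mask[, , 1] & am$valid[, , 1] & is.finite(ori)
  fit <- cos2_fit(am$r[, , 1][sel], ori[sel])
  fa <- fourier_amplitude(am$r[, , 1][sel], ori[sel])
  expect_lt(abs(fa$amplitude - fit$A / 2), 0.05 * fit$A / 2)
})

test_that("segment dipoles recover a uniform offset from the normal", {
  sc <- make_quad_scene(scene_spec(theta_d = 90, p = 0.6))
  rois <- boundary_rois(sc$truth$mask[, , 1], pixel_size = 109)
  segs <- segment_dipole(sc$quad, rois)
  ok <- segs[segs$status == "ok", ]
  expect_gt(nrow(ok), 20)
  # the membrane normal varies a few degrees across each finite ROI arc, so
  # individual segments wobble while the population centers on the preset
  expect_lt(max(circ_dist180(ok$theta_d, 90)), 5)
  expect_lt(circ_dist180(circular_mean180(ok$theta_d)$mean, 90), 1)
  # averaging dipole orientations across the ROI arc depolarizes slightly
  expect_gt(mean(ok$p), 0.5)
  expect_lt(mean(ok$p), 0.62)
})

test_that("isotropic scenes flag every segment", {
  sc <- make_quad_scene(scene_spec(p = 0))
  rois <- boundary_rois(sc$truth$mask[, , 1], pixel_size = 109)
  segs <- segment_dipole(sc$quad, rois)
  expect_true(all(segs$status %in% c("isotropic", "skipped")))
})

test_that("theta_d is invariant when the whole scene is rotated", {
  # rotating the image rotates theta_abs but the offset from the local
  # normal is unchanged; a disk rotated by 90 degrees is the same disk with
  # transposed axes
  sc <- make_quad_scene(scene_spec(theta_d = 40, p = 0.7))
  rois <- boundary_rois(sc$truth$mask[, , 1], pixel_size = 109)
  segs <- segment_dipole(sc$quad, rois)
  # transposition reflects orientations about the 45-degree axis
  # (a -> 90 - a), which maps analyzer 0 <-> 90 and fixes 45 and 135
  rot_quad <- quad_stack(
    I0 = aperm(sc$quad$I90, c(2, 1, 3)),
    I45 = aperm(sc$quad$I45, c(2, 1, 3)),
    I90 = aperm(sc$quad$I0, c(2, 1, 3)),
    I135 = aperm(sc$quad$I135, c(2, 1, 3)),
    pixel_size = 109, calibrated = TRUE)
  # transposition maps (y,x) -> (x,y): a reflection; orientations flip sign.
  # reflectional image of the same disk keeps |theta_d| structure: compare
  # medians of the angle to the normal
  rois_t <- boundary_rois(aperm(sc$truth$mask, c(2, 1, 3))[, , 1],
                          pixel_size = 109)
  segs_t <- segment_dipole(rot_quad, rois_t)
  m1 <- circular_mean180(segs$theta_d[segs$status == "ok"])$mean
  m2 <- circular_mean180(segs_t$theta_d[segs_t$status == "ok"])$mean
  expect_lt(circ_dist180(m1, fold180(-m2)), 2.5)
})

test_that("radial histogram recovers a wrapped-normal dipole population", {
  set.seed(5)
  n <- 300
  segs <- tibble::tibble(
    roi_id = seq_len(n), kind = "leading_edge",
    theta_abs = NA_real_,
    theta_d = fold180(95 + rnorm(n, 0, 10)),
    p = runif(n, 0.4, 0.8),
    total_intensity = runif(n, 500, 1500),
    n_pixels = 40L, status = "ok")
  class(segs) <- c("segment_dipoles", class(segs))
  h <- radial_histogram(segs)
  expect_lt(circ_dist180(h$mean_deg, 95), 2)
  expect_lt(abs(h$sd_deg - 10), 2)
  expect_equal(nrow(h$bins), 12)
  expect_equal(sum(h$bins$n), n)
  # doubling all weights leaves the histogram unchanged
  segs2 <- segs; segs2$total_intensity <- 2 * segs2$total_intensity
  h2 <- radial_histogram(segs2)
  expect_equal(h2$bins$mean_p, h$bins$mean_p)
  expect_equal(h2$mean_deg, h$mean_deg)
  # point mass lands in a single wedge
  segs3 <- segs; segs3$theta_d <- 95
  h3 <- radial_histogram(segs3)
  expect_equal(sum(h3$bins$n > 0), 1)
  expect_equal(h3$bins$bin_start[h3$bins$n > 0], 90)
  expect_lt(circ_dist180(h3$mean_deg, 95), 1e-6)
})

test_that("leading-edge order against a disordered body shows up in A and p", {
  # ordered dipoles only at the leading edge: per-ROI p is higher at the
  # edge than in the body
  sc <- make_quad_scene(scene_spec(theta_d = 90, p = 0.7, p_body = 0.05,
                                   total_intensity = 2000))
  res <- run_quad_pipeline(sc$quad, cell_mask = sc$truth$mask[, , 1])
  ok <- res$segments[res$segments$status == "ok", ]
  p_le <- ok$p[ok$kind == "leading_edge"]
  p_cb <- ok$p[ok$kind == "cell_body"]
  expect_gt(mean(p_le), 2 * mean(p_cb))
})
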