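test_that("threshold segmentation recovers a synthetic disk cell", {
  sc <- make_ea_scene(scene_spec(background_mean = 100, background_sd = 10,
                                 noise_model = "gaussian"))
  tot <- total_intensity(sc$pair)
  bg <- estimate_background(tot)
  ms <- segment_cells(tot, bg)
  truth <- sc$truth$mask[, , 1]
  iou <- sum(ms$cell[, , 1] & truth) / sum(ms$cell[, , 1] | truth)
  expect_gte(iou, 0.98)
})

test_that("blank images yield empty mask sets with a warning", {
  set.seed(1)
  img <- array(rnorm(128 * 128, 10, 1), c(128, 128, 1))
  bg <- estimate_background(img)
  expect_warning(ms <- segment_cells(img, bg), "no foreground")
  expect_false(any(ms$cell))
})

test_that("two disjoint cells get two labels", {
  img <- array(0, c(128, 128, 1))
  img[, , 1][test_disk(128, 128, 35, 64, 20)] <- 100
  img[, , 1][test_disk(128, 128, 95, 64, 20)] <- 100
  img <- img + 1
  bg <- structure(list(mu = 1, sigma = 0.1, threshold = 1.3,
                       mask = img < 1.3), class = "background_model")
  ms <- segment_cells(img, bg)
  expect_equal(max(ms$cell_labels), 2)
})

test_that("active-contour refinement matches the disk as well as thresholding", {
  sc <- make_ea_scene(scene_spec(background_mean = 100, background_sd = 10,
                                 noise_model = "gaussian"))
  tot <- total_intensity(sc$pair)
  bg <- estimate_background(tot)
  ms <- segment_cells(tot, bg, method = "active_contour")
  truth <- sc$truth$mask[, , 1]
  iou <- sum(ms$cell[, , 1] & truth) / sum(ms$cell[, , 1] | truth)
  expect_gte(iou, 0.95)
})

test_that("edge mask is the 10-px boundary annulus", {
  e <- edge_mask(test_disk(r = 50))
  expect_equal(sum(e), pi * (50^2 - 40^2), tolerance = 0.05)
  # containment: edge within cell
  expect_true(all(test_disk(r = 50)[e[, , 1]]))
  # cell thinner than twice the width degenerates to the whole cell
  small <- test_disk(r = 8)
  e2 <- edge_mask(small)
  expect_true(attr(e2, "degenerate")[1])
  expect_equal(sum(e2), sum(small))
  expect_error(edge_mask(matrix(FALSE, 10, 10)), "empty")
})

test_that("protrusion detection applies the area and persistence rules", {
  masks <- polorient:::scene_masks(
    scene_spec(n_frames = 10, cell_shape = "blob_protrusion"))
  pr <- detect_protrusions(masks)
  comp <- attr(pr, "components")
  expect_equal(sum(comp$kept), 1)
  expect_gte(comp$area[comp$kept], 2000)
  expect_gte(comp$persistence[comp$kept], 5)
  expect_lte(abs(comp$onset_frame[comp$kept] - 2), 1)
  # static cell: no protrusions
  static <- polorient:::scene_masks(scene_spec(n_frames = 8))
  pr0 <- detect_protrusions(static)
  expect_false(any(pr0))
  # a bump accumulating < 2000 px is rejected by the area rule
  small <- polorient:::scene_masks(
    scene_spec(n_frames = 10, cell_shape = "blob_protrusion",
               bump_radius = c(10, 25)))
  grown <- sum(small[, , 10] & !small[, , 1])
  expect_lt(grown, 2000)
  pr1 <- detect_protrusions(small)
  expect_false(any(pr1))
  expect_error(detect_protrusions(static[, , 1:3]), "6 frames")
})

test_that("leading edge is the protruding part of the edge band", {
  masks <- polorient:::scene_masks(
    scene_spec(n_frames = 10, cell_shape = "blob_protrusion"))
  e <- edge_mask(masks)
  pr <- detect_protrusions(masks)
  le <- leading_edge_mask(e, pr)
  # containment chain
  expect_true(all(e[le]))
  expect_gt(sum(le[, , 10]), 0)
  # the leading edge sits on the protruding (east) side only
  idx <- which(le[, , 10], arr.ind = TRUE)
  expect_gt(min(idx[, 2]), ncol(masks[, , 1]) / 2)
  # no protrusions -> empty leading edge
  le0 <- leading_edge_mask(e, pr & FALSE)
  expect_false(any(le0))
})

test_that("boundary ROI count matches the perimeter of the disk", {
  r_px <- 5000 / 109
  m <- test_disk(220, 220, 110, 110, r_px)
  rois <- boundary_rois(m, pixel_size = 109)
  expect_lte(abs(nrow(rois) - floor(2 * pi * 5000 / 1000)), 2)
  # normals differ from tangents by exactly 90 degrees
  expect_equal(fold180(rois$normal_deg - rois$tangent_deg),
               rep(90, nrow(rois)))
})

test_that("ROI tangents follow the local membrane on a disk", {
  m <- test_disk(220, 220, 110, 110, 45)
  rois <- boundary_rois(m, pixel_size = 109)
  # tangent should be perpendicular to the outward radial direction
  az <- raster_angle(rois$cx - 110, rois$cy - 110)
  dev <- circ_dist180(rois$tangent_deg, fold180(az + 90))
  expect_lt(max(dev), 8)
  expect_lt(mean(dev), 3)
  # adjacent tangents vary smoothly on a convex shape
  step <- circ_dist180(rois$tangent_deg[-1],
                       rois$tangent_deg[-nrow(rois)])
  expect_lt(max(step), 15)
})

test_that("square-cell ROI tangents align with the four side orientations", {
  m <- matrix(FALSE, 160, 160)
  m[40:120, 40:120] <- TRUE
  rois <- boundary_rois(m, pixel_size = 109)
  # away from corners the tangent must be 0 or 90
  dev <- pmin(circ_dist180(rois$tangent_deg, 0),
              circ_dist180(rois$tangent_deg, 90))
  expect_lt(stats::median(dev), 2)
})

test_that("cell-body ROIs sit > 1000 nm inside with the same tangents", {
  m <- test_disk(220, 220, 110, 110, 70)
  le <- boundary_rois(m, pixel_size = 109, kind = "leading_edge")
  cb <- boundary_rois(m, pixel_size = 109, kind = "cell_body")
  expect_equal(nrow(le), nrow(cb))
  expect_equal(le$tangent_deg, cb$tangent_deg)
  d_le <- sqrt((le$cx - 110)^2 + (le$cy - 110)^2)
  d_cb <- sqrt((cb$cx - 110)^2 + (cb$cy - 110)^2)
  expect_true(all((d_le - d_cb) * 109 > 1000))
})
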