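# Mask chain for migrating cells: cell -> edge -> protrusion -> leading edge,
# plus membrane-tangent boundary ROIs. All masks are logical arrays with
# dim = c(ny, nx, n_frames).

disc_brush <- function(radius) EBImage::makeBrush(2L * radius + 1L, "disc")

label_mask <- function(m) EBImage::bwlabel(m * 1)

#' Segment cells from a total-intensity stack
#'
#' Background-mask regions (pixels above the background threshold) seed the
#' segmentation; seeds are expanded by a 5-pixel dilation so that local
#' background is retained for contrast, then either threshold segmentation
#' (default) or a Chan-Vese-style active contour refines each cell.
#' Morphological cleanup applies a closure of radius 1, removal of objects
#' smaller than `min_area`, and hole filling. For movies, only cells
#' consistently segmented in at least `min_frames` frames (tracked by
#' frame-to-frame overlap within a spatiotemporal bounding box) are kept.
#'
#' @param total intensity matrix or stack (`ny x nx x n_frames`).
#' @param bg a `background_model` from [estimate_background].
#' @param method `"threshold"` or `"active_contour"`.
#' @param min_area smallest object kept, px.
#' @param min_frames persistence required in movies (ignored when
#'   `n_frames < min_frames`).
#' @param ac_iter,ac_smooth active-contour iterations and smoothing radius.
#' @return object of class `mask_set` (so far holding only `cell`): list of
#'   logical arrays; `cell_labels` holds per-frame integer labels.
#' @export
segment_cells <- function(total, bg, method = c("threshold", "active_contour"),
                          min_area = 50, min_frames = 5,
                          ac_iter = 20, ac_smooth = 2) {
  method <- match.arg(method)
  total <- as_stack(total, "total")
  nf <- dim(total)[3]
  cell <- array(FALSE, dim(total))
  for (i in seq_len(nf)) {
    f <- total[, , i]
    fg <- f > bg$threshold
    if (!any(fg)) next
    seed <- EBImage::dilate(fg * 1, disc_brush(5)) > 0
    m <- if (method == "threshold") {
      fg & seed
    } else {
      chan_vese(f, seed, iter = ac_iter, smooth = ac_smooth)
    }
    m <- EBImage::closing(m * 1, disc_brush(1)) > 0
    lab <- label_mask(m)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_area)
    m <- array(lab %in% keep, dim(lab))
    m <- EBImage::fillHull(m * 1) > 0
    cell[, , i] <- m
  }
  if (nf >= min_frames) cell <- persistent_components(cell, min_frames)
  if (!any(cell)) warn("no foreground found; mask set is empty")
  labels <- array(0L, dim(cell))
  for (i in seq_len(nf)) labels[, , i] <- label_mask(cell[, , i])
  structure(list(cell = cell, cell_labels = labels,
                 params = list(method = method, min_area = min_area,
                               min_frames = min_frames)),
            class = "mask_set")
}

# Minimal two-phase Chan-Vese refinement: alternate between region means and
# reassignment, with morphological smoothing.
chan_vese <- function(f, init, iter = 20, smooth = 2) {
  m <- init
  for (k in seq_len(iter)) {
    if (!any(m) || all(m)) break
    c1 <- mean(f[m]); c2 <- mean(f[!m])
    m2 <- (f - c1)^2 < (f - c2)^2
    if (smooth > 0) m2 <- EBImage::closing(EBImage::opening(m2 * 1, disc_brush(smooth)),
                                           disc_brush(smooth)) > 0
    if (identical(m2, m)) break
    m <- m2
  }
  m
}

# Track per-frame components by overlap; drop tracks seen < min_frames times.
persistent_components <- function(mask, min_frames) {
  nf <- dim(mask)[3]
  labs <- vector("list", nf)
  offs <- integer(nf)
  nxt <- 0L
  for (i in seq_len(nf)) {
    l <- label_mask(mask[, , i])
    offs[i] <- nxt
    l[l > 0] <- l[l > 0] + nxt
    nxt <- max(nxt, suppressWarnings(max(l)))
    labs[[i]] <- l
  }
  parent <- seq_len(max(1L, nxt))
  find <- function(a) { while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }; a }
  union2 <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[rb] <<- ra }
  for (i in seq_len(nf - 1L)) {
    ov <- labs[[i]] > 0 & labs[[i + 1L]] > 0
    if (!any(ov)) next
    pairs <- unique(cbind(labs[[i]][ov], labs[[i + 1L]][ov]))
    for (j in seq_len(nrow(pairs))) union2(pairs[j, 1], pairs[j, 2])
  }
  if (nxt == 0L) return(mask)
  roots <- vapply(seq_len(nxt), find, integer(1))
  frames_seen <- lapply(seq_len(nf), function(i) unique(roots[setdiff(unique(as.integer(labs[[i]])), 0L)]))
  counts <- table(unlist(frames_seen))
  good <- as.integer(names(counts)[counts >= min_frames])
  out <- array(FALSE, dim(mask))
  for (i in seq_len(nf)) out[, , i] <- array(roots[pmax(labs[[i]], 1L)] %in% good & labs[[i]] > 0,
                                             dim(labs[[i]]))
  out
}

#' Edge band of a cell mask
#'
#' The cell mask is eroded by `width` pixels and inversely combined with the
#' original mask, leaving a band of `width` px along the boundary. Cells too
#' thin to survive the erosion yield the whole cell as edge, with a flag.
#'
#' @param cell logical matrix or stack of cell masks.
#' @param width erosion radius, px (default 10).
#' @return logical array of the same shape with attribute `degenerate`
#'   (logical per frame: TRUE where erosion emptied the cell).
#' @export
edge_mask <- function(cell, width = 10) {
  cell <- as_stack(cell, "cell") > 0
  if (!any(cell)) abort("empty cell mask")
  nf <- dim(cell)[3]
  out <- array(FALSE, dim(cell))
  degen <- logical(nf)
  br <- disc_brush(width)
  for (i in seq_len(nf)) {
    m <- cell[, , i]
    if (!any(m)) next
    er <- EBImage::erode(m * 1, br) > 0
    if (!any(er)) {
      out[, , i] <- m
      degen[i] <- TRUE
    } else {
      out[, , i] <- m & !er
    }
  }
  attr(out, "degenerate") <- degen
  out
}

#' Detect protrusions in a cell-mask movie
#'
#' Positive frame-to-frame differences of the cell mask (newly occupied
#' pixels) are linked into spatiotemporal connected components (8-connected
#' in space, adjacent in time); components are kept when their accumulated
#' positive area reaches `min_area` pixels and they persist for at least
#' `min_frames` frames.
#'
#' @param cell logical stack of cell masks, at least 6 frames.
#' @param min_area accumulated positive area threshold, px (default 2000).
#' @param min_frames persistence threshold, frames (default 5).
#' @return logical stack of per-frame protrusion masks (frame 1 empty), with
#'   attribute `components`: tibble of component id, area, onset frame,
#'   persistence.
#' @export
detect_protrusions <- function(cell, min_area = 2000, min_frames = 5) {
  cell <- as_stack(cell, "cell") > 0
  nf <- dim(cell)[3]
  if (nf < 6L) abort("protrusion detection needs at least 6 frames")
  pos <- array(FALSE, dim(cell))
  for (i in 2:nf) pos[, , i] <- cell[, , i] & !cell[, , i - 1L]
  # spatiotemporal linking: per-frame labels unioned across adjacent frames
  # (1 px spatial dilation when testing temporal adjacency)
  labs <- vector("list", nf); nxt <- 0L
  for (i in seq_len(nf)) {
    l <- label_mask(pos[, , i])
    l[l > 0] <- l[l > 0] + nxt
    nxt <- max(nxt, suppressWarnings(max(l)))
    labs[[i]] <- l
  }
  if (nxt == 0L) {
    out <- pos & FALSE
    attr(out, "components") <- tibble(component = integer(), area = integer(),
                                      onset_frame = integer(),
                                      persistence = integer(), kept = logical())
    return(out)
  }
  parent <- seq_len(nxt)
  find <- function(a) { while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }; a }
  union2 <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[rb] <<- ra }
  for (i in seq_len(nf - 1L)) {
    la <- labs[[i]]; lb <- labs[[i + 1L]]
    if (!any(la > 0) || !any(lb > 0)) next
    grown <- EBImage::dilate((la > 0) * 1, disc_brush(1)) > 0
    ov <- grown & lb > 0
    if (!any(ov)) next
    # map each overlapping b-label to the nearest a-label via the dilated support
    bl <- unique(lb[ov])
    for (b in bl) {
      sel <- lb == b & grown
      al <- unique(la[EBImage::dilate(sel * 1, disc_brush(1)) > 0 & la > 0])
      for (a in al) union2(a, b)
    }
  }
  roots <- vapply(seq_len(nxt), find, integer(1))
  area <- setNames(integer(length(unique(roots))), as.character(unique(roots)))
  frames_by_root <- list()
  for (i in seq_len(nf)) {
    l <- labs[[i]]
    present <- setdiff(unique(as.integer(l)), 0L)
    for (lab in present) {
      rt <- as.character(roots[lab])
      area[rt] <- area[rt] + sum(l == lab)
      frames_by_root[[rt]] <- c(frames_by_root[[rt]], i)
    }
  }
  persistence <- vapply(frames_by_root, function(f) length(unique(f)), integer(1))
  onset <- vapply(frames_by_root, min, integer(1))
  keep_roots <- as.integer(names(area))[area >= min_area &
                                          persistence[names(area)] >= min_frames]
  out <- array(FALSE, dim(cell))
  for (i in seq_len(nf)) {
    l <- labs[[i]]
    out[, , i] <- array(l > 0 & roots[pmax(l, 1L)] %in% keep_roots, dim(l))
  }
  root_ids <- names(area)   # snapshot before tibble's data masking kicks in
  comp <- tibble(component = as.integer(root_ids),
                 area = as.integer(unname(area[root_ids])),
                 onset_frame = unname(onset[root_ids]),
                 persistence = unname(persistence[root_ids]),
                 kept = as.integer(root_ids) %in% keep_roots)
  attr(out, "components") <- comp
  out
}

#' Leading-edge mask
#'
#' The leading edge is the part of the edge band that belongs to a positive
#' protrusion: per frame, the intersection of the edge mask with the
#' spatiotemporal support (union over frames) of accepted protrusion
#' components.
#'
#' @param edge logical stack from [edge_mask].
#' @param protrusions logical stack from [detect_protrusions].
#' @return logical stack.
#' @export
leading_edge_mask <- function(edge, protrusions) {
  edge <- as_stack(edge, "edge") > 0
  protrusions <- as_stack(protrusions, "protrusions") > 0
  if (!identical(dim(edge), dim(protrusions)))
    abort("edge and protrusion masks must share the frame grid")
  support <- apply(protrusions, c(1, 2), any)
  out <- array(FALSE, dim(edge))
  for (i in seq_len(dim(edge)[3])) out[, , i] <- edge[, , i] & support
  out
}

extract_boundary <- function(mask, smooth_window = 9L) {
  # ordered boundary contour of the largest object, as a (y, x) matrix;
  # a circular boxcar over a few contour points irons out single-pixel
  # staircase steps so tangents vary smoothly along the membrane
  oc <- EBImage::ocontour(EBImage::Image(mask * 1))
  if (length(oc) == 0L) abort("no boundary extractable from the mask")
  pts <- oc[[which.max(vapply(oc, nrow, integer(1)))]]
  # EBImage coordinates are 0-based along (dim1, dim2) = (row, col)
  bd <- cbind(y = pts[, 1] + 1, x = pts[, 2] + 1)
  n <- nrow(bd)
  if (smooth_window > 1L && n > 2L * smooth_window) {
    k <- smooth_window %/% 2L
    idx <- outer(seq_len(n), -k:k, function(i, o) ((i + o - 1L) %% n) + 1L)
    bd <- cbind(y = rowMeans(matrix(bd[idx, "y"], n)),
                x = rowMeans(matrix(bd[idx, "x"], n)))
  }
  bd
}

#' Boundary ROIs with membrane tangent and normal
#'
#' Tiles non-overlapping rectangles of physical size `roi_length` x
#' `roi_width` (default 1000 x 500 nm) along the cell boundary, long axis
#' tangential to the membrane. The tangent at each ROI is the principal axis
#' of the boundary points within +/- `roi_length/2` of arc length; the
#' normal is tangent + 90 degrees, with the outward sense fixed away from
#' the cell centroid. Cell-body ROIs reuse the same long-axis angles but are
#' displaced inward along the normal by `body_depth` (> 1000 nm from the
#' boundary).
#'
#' @param cell logical cell mask (single frame).
#' @param pixel_size nm per px.
#' @param kind `"leading_edge"` (on the boundary) or `"cell_body"` (inset).
#' @param roi_length,roi_width ROI size in nm.
#' @param body_depth inward displacement of cell-body ROIs, nm.
#' @param start_near optional `c(x, y)`: start tiling at the boundary point
#'   nearest this point (e.g. a protrusion centroid); default = first
#'   contour point. The leftover arc shorter than one ROI is dropped.
#' @param restrict_to optional logical mask: keep only ROIs whose center
#'   (for `leading_edge`, the boundary point) falls inside it, e.g. a
#'   leading-edge mask.
#' @return tibble of class `boundary_rois`: `roi_id`, `cx`, `cy` (px),
#'   `tangent_deg`, `normal_deg` (`[0,180)`), `outward_deg` (`[0,360)`),
#'   `kind`, `length_px`, `width_px`.
#' @export
boundary_rois <- function(cell, pixel_size = 109,
                          kind = c("leading_edge", "cell_body"),
                          roi_length = 1000, roi_width = 500,
                          body_depth = 1250, start_near = NULL,
                          restrict_to = NULL) {
  kind <- match.arg(kind)
  if (length(dim(cell)) == 3L) cell <- cell[, , 1]
  if (!any(cell)) abort("empty cell mask")
  bd <- extract_boundary(cell)
  n <- nrow(bd)
  len_px <- roi_length / pixel_size
  wid_px <- roi_width / pixel_size
  seg <- sqrt(diff(c(bd[, "x"], bd[1, "x"]))^2 + diff(c(bd[, "y"], bd[1, "y"]))^2)
  arc <- cumsum(c(0, seg[-n]))
  per <- sum(seg)
  n_roi <- floor(per * pixel_size / roi_length)
  if (n_roi < 1L) return(empty_roi_tbl())
  start_i <- 1L
  if (!is.null(start_near)) {
    d2 <- (bd[, "x"] - start_near[1])^2 + (bd[, "y"] - start_near[2])^2
    start_i <- which.min(d2)
  }
  # re-origin arc length at the start point
  arc0 <- (arc - arc[start_i]) %% per
  cy0 <- mean(row(cell)[cell]); cx0 <- mean(col(cell)[cell])
  half_arc_px <- (roi_length / 2) / pixel_size
  rows <- vector("list", n_roi)
  for (k in seq_len(n_roi)) {
    target <- (k - 0.5) * len_px
    i <- which.min(abs(arc0 - target))
    # boundary points within +/- half ROI length of arc distance
    d <- pmin(abs(arc0 - arc0[i]), per - abs(arc0 - arc0[i]))
    nb <- bd[d <= half_arc_px, , drop = FALSE]
    tangent <- principal_axis_angle(nb[, "x"], -nb[, "y"])
    cxy <- c(bd[i, "x"], bd[i, "y"])
    outward <- atan2(-(cxy[2] - cy0), cxy[1] - cx0) * 180 / pi
    # outward normal: the normal direction (tangent + 90) whose display
    # vector points away from the centroid
    nrm <- fold180(tangent + 90)
    cand <- c(nrm, nrm + 180)
    dd <- abs(((cand - outward + 180) %% 360) - 180)
    outward_deg <- cand[which.min(dd)] %% 360
    if (kind == "cell_body") {
      dxy <- c(cos(outward_deg * pi / 180), -sin(outward_deg * pi / 180))
      cxy <- cxy - dxy * body_depth / pixel_size
    }
    rows[[k]] <- tibble(roi_id = k, cx = cxy[1], cy = cxy[2],
                        tangent_deg = tangent, normal_deg = nrm,
                        outward_deg = outward_deg, kind = kind,
                        length_px = len_px, width_px = wid_px)
  }
  out <- dplyr::bind_rows(rows)
  if (!is.null(restrict_to)) {
    if (length(dim(restrict_to)) == 3L) restrict_to <- restrict_to[, , 1]
    ok <- restrict_to[cbind(pmin(pmax(round(out$cy), 1), nrow(restrict_to)),
                            pmin(pmax(round(out$cx), 1), ncol(restrict_to)))]
    out <- out[ok, , drop = FALSE]
  }
  class(out) <- c("boundary_rois", class(out))
  out
}

empty_roi_tbl <- function() {
  tibble(roi_id = integer(), cx = double(), cy = double(),
         tangent_deg = double(), normal_deg = double(),
         outward_deg = double(), kind = character(),
         length_px = double(), width_px = double())
}

# orientation (deg, [0,180)) of the principal axis of 2D points given in
# display coordinates (x right, y up)
principal_axis_angle <- function(x, y) {
  x <- x - mean(x); y <- y - mean(y)
  sxx <- mean(x^2); syy <- mean(y^2); sxy <- mean(x * y)
  fold180(0.5 * atan2(2 * sxy, sxx - syy) * 180 / pi)
}

#' Pixel membership mask of a boundary ROI
#'
#' @param roi one row of a [boundary_rois] tibble.
#' @param dim image dimensions `c(ny, nx)`.
#' @return logical matrix, TRUE inside the rotated rectangle.
#' @export
roi_mask <- function(roi, dim) {
  ny <- dim[1]; nx <- dim[2]
  a <- roi$tangent_deg * pi / 180
  tx <- cos(a); ty <- -sin(a)          # tangent in raster coords
  nx_ <- -ty; ny_ <- tx                # normal in raster coords
  X <- matrix(rep(seq_len(nx), each = ny), ny, nx)
  Y <- matrix(rep(seq_len(ny), nx), ny, nx)
  dx <- X - roi$cx; dy <- Y - roi$cy
  along <- dx * tx + dy * ty
  across <- dx * nx_ + dy * ny_
  abs(along) <= roi$length_px / 2 & abs(across) <= roi$width_px / 2
}
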