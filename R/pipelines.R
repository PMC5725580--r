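# End-to-end pipeline drivers tying calibration, segmentation and analysis
# together, plus a file-based runner with a provenance manifest.

#' Run the full two-channel (anisotropy) analysis chain
#'
#' Background estimation on the total intensity, anisotropy with the 3x3
#' intensity-weighted prefilter, cell/edge (and, for movies, protrusion and
#' leading-edge) segmentation, orientation map, and per-region cos-squared
#' fits with the SNR-5 exclusion rule.
#'
#' @param pair a [polar_pair].
#' @param frame frame to fit (default: last).
#' @param bin_width orientation bin width, degrees.
#' @param prefilter logical, 3x3 intensity-weighted prefilter.
#' @param mode cos-squared fit mode, see [cos2_fit].
#' @param edge_width edge-band erosion radius, px.
#' @param min_area smallest protrusion kept, px; @param min_frames its
#'   persistence threshold.
#' @return list of class `ea_result`: `fits` (per-region tibble), `amap`,
#'   `masks`, `orientation`, `background`.
#' @export
run_ea_pipeline <- function(pair, frame = NULL, bin_width = 10,
                            prefilter = TRUE, mode = "binned",
                            edge_width = 10, min_area = 2000,
                            min_frames = 5) {
  stopifnot(inherits(pair, "polar_pair"))
  total <- total_intensity(pair)
  nf <- dim(total)[3]
  if (is.null(frame)) frame <- nf
  bg <- estimate_background(total)
  amap <- anisotropy(pair, bg, prefilter = prefilter)
  ms <- segment_cells(total, bg)
  regions <- list(cell = ms$cell)
  edge <- NULL
  if (any(ms$cell)) {
    edge <- edge_mask(ms$cell, width = edge_width)
    regions$edge <- edge
    if (nf >= 6L) {
      prot <- detect_protrusions(ms$cell, min_area = min_area,
                                 min_frames = min_frames)
      if (any(prot)) {
        regions$protrusion <- prot
        regions$leading_edge <- leading_edge_mask(edge, prot)
      }
    }
  }
  fits <- region_cos_fits(amap, regions, cell_mask = ms$cell, bg = bg,
                          perp = pair$perpendicular, frame = frame,
                          bin_width = bin_width, mode = mode)
  ori <- if (any(ms$cell[, , frame])) orientation_map(ms$cell[, , frame]) else NULL
  structure(list(fits = fits, amap = amap, masks = regions,
                 orientation = ori, background = bg, frame = frame),
            class = "ea_result")
}

#' @export
print.ea_result <- function(x, ...) {
  cat("<ea_result> per-region cos^2 fits:\n")
  print(as.data.frame(x$fits))
  invisible(x)
}

#' Run the full four-channel (dipole orientation) analysis chain
#'
#' Segments the cell from total intensity, tiles 1000 x 500 nm boundary
#' ROIs along the leading edge (long axis tangential to the membrane) and
#' matching cell-body ROIs > 1000 nm inside, computes per-ROI dipole
#' orientation and polarization factor from the channel sums, and builds
#' the intensity-weighted radial histogram of `theta_d` with its
#' circular-Gaussian fit.
#'
#' @param quad a calibrated [quad_stack].
#' @param frame frame to analyze.
#' @param cell_mask optional logical mask; segmented from total intensity
#'   when NULL.
#' @param leading_edge_mask optional logical mask restricting leading-edge
#'   ROIs to the protruding boundary.
#' @param roi_length,roi_width ROI size, nm; @param body_depth cell-body
#'   inset, nm.
#' @return list of class `quad_result`: `segments` (tibble of all ROIs),
#'   `histograms` (named list of `radial_histogram` per ROI kind), `rois`.
#' @export
run_quad_pipeline <- function(quad, frame = 1L, cell_mask = NULL,
                              leading_edge_mask = NULL,
                              roi_length = 1000, roi_width = 500,
                              body_depth = 1250) {
  stopifnot(inherits(quad, "quad_stack"))
  total <- total_intensity(quad)
  if (is.null(cell_mask)) {
    bg <- estimate_background(total)
    ms <- segment_cells(total, bg)
    cell_mask <- ms$cell[, , frame]
  } else if (length(dim(cell_mask)) == 3L) cell_mask <- cell_mask[, , frame]
  if (!any(cell_mask)) abort("no cell found in the four-channel stack")
  rois_le <- boundary_rois(cell_mask, pixel_size = quad$pixel_size,
                           kind = "leading_edge", roi_length = roi_length,
                           roi_width = roi_width,
                           restrict_to = leading_edge_mask)
  rois_cb <- boundary_rois(cell_mask, pixel_size = quad$pixel_size,
                           kind = "cell_body", roi_length = roi_length,
                           roi_width = roi_width, body_depth = body_depth)
  rois_cb$roi_id <- rois_cb$roi_id + nrow(rois_le)
  rois <- dplyr::bind_rows(rois_le, rois_cb)
  segs <- segment_dipole(quad, rois, frame = frame)
  hists <- lapply(split(segs, segs$kind), function(s)
    tryCatch(radial_histogram(s), error = function(e) NULL))
  structure(list(segments = segs, histograms = hists, rois = rois,
                 frame = frame),
            class = "quad_result")
}

#' @export
print.quad_result <- function(x, ...) {
  cat(sprintf("<quad_result> %d ROIs (%d ok)\n", nrow(x$segments),
              sum(x$segments$status == "ok")))
  for (k in names(x$histograms)) {
    h <- x$histograms[[k]]
    if (!is.null(h))
      cat(sprintf("  %s: mean theta_d = %.1f deg (sd %.1f), mean p = %.3f\n",
                  k, h$mean_deg, h$sd_deg,
                  mean(x$segments$p[x$segments$kind == k &
                                      x$segments$status == "ok"])))
  }
  invisible(x)
}

#' Run the actin-flow analysis chain
#'
#' Lucas-Kanade optical flow on the movie, per-boundary-ROI flow averaging
#' against the membrane tangent, and the direction histogram with Gaussian
#' fit.
#'
#' @param stack movie array.
#' @param rois a [boundary_rois] tibble (e.g. along the leading edge).
#' @param pixel_size nm; @param frame_interval s.
#' @param ... passed to [lucas_kanade_flow].
#' @return list of class `flow_result`: `field`, `segments`, `histogram`.
#' @export
run_flow_pipeline <- function(stack, rois, pixel_size = 109,
                              frame_interval = 1, ...) {
  field <- lucas_kanade_flow(stack, pixel_size = pixel_size,
                             frame_interval = frame_interval, ...)
  segs <- flow_by_segment(field, rois)
  hist <- tryCatch(direction_histogram(segs), error = function(e) NULL)
  structure(list(field = field, segments = segs, histogram = hist),
            class = "flow_result")
}

#' File-based pipeline runner with provenance manifest
#'
#' Reads the modality's channels from multi-page TIFFs, executes the full
#' chain, and writes CSV result tables plus a machine-readable JSON
#' manifest echoing every parameter, the package version and input
#' checksums, so two runs with identical config and inputs are
#' byte-identical.
#'
#' @param config named list: `modality` (`"ea"`, `"quad"` or `"flow"`),
#'   `paths` (named list of channel TIFFs: `parallel`/`perpendicular`, or
#'   `I0`/`I45`/`I90`/`I135`, or `movie`), `out_dir`, `pixel_size`,
#'   `frame_interval`, `g_factor`, `seed`, and any parameters of the
#'   underlying pipeline (passed through).
#' @return the pipeline result, invisibly; side effect: files in
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  need <- c("modality", "paths", "out_dir")
  if (!all(need %in% names(config)))
    abort(sprintf("config must name: %s", paste(need, collapse = ", ")))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  px <- config$pixel_size %||% 109
  fi <- config$frame_interval %||% 1
  if (!is.null(config$seed)) set.seed(config$seed)
  res <- switch(
    config$modality,
    ea = {
      pair <- polar_pair(read_stack_tiff(config$paths$parallel),
                         read_stack_tiff(config$paths$perpendicular),
                         g_factor = config$g_factor %||% 1, pixel_size = px)
      r <- run_ea_pipeline(pair, bin_width = config$bin_width %||% 10)
      write_table(r$fits, file.path(config$out_dir, "region_fits.csv"))
      r
    },
    quad = {
      quad <- quad_stack(read_stack_tiff(config$paths$I0),
                         read_stack_tiff(config$paths$I45),
                         read_stack_tiff(config$paths$I90),
                         read_stack_tiff(config$paths$I135),
                         throughput = config$throughput %||% c(1, 1, 1, 1),
                         pixel_size = px, calibrated = TRUE)
      r <- run_quad_pipeline(quad)
      write_table(r$segments, file.path(config$out_dir, "segment_dipoles.csv"))
      for (k in names(r$histograms)) {
        if (!is.null(r$histograms[[k]]))
          write_table(r$histograms[[k]]$bins,
                      file.path(config$out_dir, paste0("radial_hist_", k, ".csv")))
      }
      r
    },
    flow = {
      stack <- read_stack_tiff(config$paths$movie)
      bg <- estimate_background(stack)
      ms <- segment_cells(stack, bg)
      rois <- boundary_rois(ms$cell[, , 1], pixel_size = px)
      r <- run_flow_pipeline(stack, rois, pixel_size = px, frame_interval = fi)
      write_table(r$segments, file.path(config$out_dir, "segment_flow.csv"))
      if (!is.null(r$histogram))
        write_table(r$histogram$bins,
                    file.path(config$out_dir, "direction_histogram.csv"))
      r
    },
    abort(sprintf("unknown modality '%s'", config$modality))
  )
  manifest <- list(
    package = "polorient",
    version = as.character(utils::packageVersion("polorient")),
    config = config[setdiff(names(config), "paths")],
    inputs = lapply(config$paths, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
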