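# File I/O: multi-page TIFF stacks, CSV result tables, scene sidecars and
# run manifests.

#' Read a multi-page TIFF into a stack array
#'
#' Reads all pages into a `ny x nx x n_frames` array. Stacks written by
#' [write_stack_tiff] are restored to their original intensity range via
#' the `<path>.meta.json` sidecar; foreign TIFFs come back in the `[0, 1]`
#' convention of the underlying reader.
#'
#' @param path TIFF file.
#' @return `ny x nx x n_frames` numeric array.
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (is.matrix(pages)) pages <- list(pages)
  arr <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    if (length(dim(p)) == 3L) p <- p[, , 1]
    arr[, , i] <- p
  }
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path)
    arr <- arr * (meta$hi - meta$lo) + meta$lo
  }
  arr
}

#' Write a stack array as 32-bit multi-page TIFF
#'
#' Intensities are stored scaled to `[0, 1]` at 32-bit depth (about 1e-9
#' relative resolution); the original range is recorded in a
#' `<path>.meta.json` sidecar that [read_stack_tiff] uses to restore the
#' raw values.
#'
#' @param stack matrix or `ny x nx x n_frames` array.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  stack <- as_stack(stack, "stack")
  lo <- min(stack); hi <- max(stack)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(stack)[3]),
                  function(i) (stack[, , i] - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "deflate")
  jsonlite::write_json(list(lo = lo, hi = lo + scale),
                       paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write a synthetic scene to disk (TIFF channels + JSON sidecar)
#'
#' Writes one multi-page TIFF per channel, the ground-truth fields as
#' additional TIFFs, and a JSON sidecar holding the generation spec.
#'
#' @param scene an `ea_scene`, `quad_scene` or `flow_scene`.
#' @param dir output directory (created if missing).
#' @param name file-name stem.
#' @return tibble of the files written, invisibly.
#' @export
write_scene <- function(scene, dir, name = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  put <- function(stack, suffix) {
    f <- file.path(dir, paste0(name, "_", suffix, ".tif"))
    s <- stack
    s[is.na(s)] <- -1
    write_stack_tiff(s, f)
    files <<- c(files, f)
  }
  if (inherits(scene, "ea_scene")) {
    put(scene$pair$parallel, "parallel")
    put(scene$pair$perpendicular, "perpendicular")
    put(scene$truth$orientation, "truth_orientation")
    put(scene$truth$r, "truth_r")
    put(scene$truth$mask * 1, "truth_mask")
    spec <- scene$truth$spec
  } else if (inherits(scene, "quad_scene")) {
    for (k in c("I0", "I45", "I90", "I135")) put(scene$quad[[k]], k)
    put(scene$truth$theta, "truth_theta")
    put(scene$truth$p, "truth_p")
    put(scene$truth$mask * 1, "truth_mask")
    spec <- scene$truth$spec
  } else if (inherits(scene, "flow_scene")) {
    put(scene$stack, "movie")
    spec <- list(vx = scene$truth$vx, vy = scene$truth$vy,
                 pixel_size = scene$pixel_size,
                 frame_interval = scene$frame_interval)
  } else abort("unknown scene type")
  sidecar <- file.path(dir, paste0(name, "_spec.json"))
  jsonlite::write_json(unclass(spec), sidecar, auto_unbox = TRUE, digits = NA,
                       null = "null")
  files <- c(files, sidecar)
  invisible(tibble(file = files))
}

write_table <- function(x, path) {
  readr::write_csv(as_tibble(x), path)
  invisible(path)
}
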