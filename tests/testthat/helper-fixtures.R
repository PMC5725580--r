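# Shared fixtures built in code at test time.

# small disk mask helper (matches the generator's geometry)
test_disk <- function(ny = 128, nx = 128, cx = nx / 2, cy = ny / 2, r = 45) {
  X <- matrix(rep(seq_len(nx), each = ny), ny, nx)
  Y <- matrix(rep(seq_len(ny), nx), ny, nx)
  (X - cx)^2 + (Y - cy)^2 <= r^2
}

# Gaussian bead image: point sources at given (x, y) centers
bead_image <- function(ny, nx, centers, sigma = 1) {
  m <- matrix(0, ny, nx)
  for (i in seq_len(nrow(centers))) {
    cx <- centers[i, 1]; cy <- centers[i, 2]
    xs <- max(1, round(cx) - 4):min(nx, round(cx) + 4)
    ys <- max(1, round(cy) - 4):min(ny, round(cy) + 4)
    for (yy in ys) for (xx in xs)
      m[yy, xx] <- m[yy, xx] +
        exp(-((xx - cx)^2 + (yy - cy)^2) / (2 * sigma^2))
  }
  m
}

# Monte-Carlo oracle for the ensemble polarization factor: independent of
# ensemble_dipole()'s code path, it sums the same photoselection physics
# directly over an explicit angle grid.
mc_p_oracle <- function(angles_deg, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(angles_deg))
  I <- vapply(c(0, 45, 90, 135), function(a)
    sum(weights * cos((a - angles_deg) * pi / 180)^2), numeric(1))
  sqrt((I[1] - I[3])^2 + (I[2] - I[4])^2) / (0.5 * sum(I))
}
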