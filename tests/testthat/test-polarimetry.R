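test_that("anisotropy formula reproduces the closed-form identities", {
  mk <- function(par, perp) polar_pair(matrix(par, 2, 2), matrix(perp, 2, 2))
  r_of <- function(par, perp)
    anisotropy(mk(par, perp), bg = NULL, prefilter = FALSE)$r[1, 1, 1]
  expect_equal(r_of(5, 5), 0)          # equal channels
  expect_equal(r_of(7, 0), 1)          # no perpendicular emission
  expect_equal(r_of(0, 3), -0.5)       # no parallel emission
  expect_equal(r_of(3, 1), 0.4)        # direct substitution
})

test_that("anisotropy stays in [-0.5, 1] for any nonnegative inputs", {
  set.seed(11)
  n <- 1000
  par <- array(runif(n * n, 0, 1000), c(n, n, 1))
  perp <- array(runif(n * n, 0, 1000), c(n, n, 1))
  am <- anisotropy(polar_pair(par, perp), bg = NULL, prefilter = FALSE)
  r <- am$r[am$valid]
  expect_true(all(r >= -0.5 & r <= 1))
  expect_gt(length(r), 0.99 * n * n)
})

test_that("zero total intensity is marked invalid, not propagated", {
  par <- matrix(c(0, 3), 1, 2); perp <- matrix(c(0, 1), 1, 2)
  am <- anisotropy(polar_pair(par, perp), bg = NULL, prefilter = FALSE)
  expect_false(am$valid[1, 1, 1])
  expect_true(is.na(am$r[1, 1, 1]))
  expect_equal(am$r[1, 2, 1], 0.4)
})

test_that("3x3 prefilter is an intensity-weighted neighborhood average", {
  # two-intensity checkerboard: the weighted average must favor the
  # brighter pixels
  par <- matrix(2, 9, 9); perp <- matrix(1, 9, 9)   # dim pixels: r = 0.25
  par[5, 5] <- 40; perp[5, 5] <- 0    # bright r = 1 pixel at the center
  am <- anisotropy(polar_pair(par, perp), bg = NULL, prefilter = TRUE)
  # manual weighted average at the center: w = Ipar + 2 Iperp
  w_bright <- 40; w_dim <- 4
  r_expect <- (w_bright * 1 + 8 * w_dim * 0.25) / (w_bright + 8 * w_dim)
  expect_equal(am$r[5, 5, 1], r_expect)
})

test_that("background estimator recovers a half-Gaussian left shoulder", {
  set.seed(1)
  img <- matrix(rnorm(300 * 300, 100, 10), 300, 300)
  b <- estimate_background(img)
  expect_lt(abs(b$mu - 100) / 100, 0.02)
  expect_lt(abs(b$sigma - 10) / 10, 0.05)
  expect_equal(b$threshold, b$mu + 3 * b$sigma)
  # a bright foreground blob must not move the estimate by more than 2%
  img2 <- img; img2[100:180, 100:180] <- 1e4
  b2 <- estimate_background(img2)
  expect_lt(abs(b2$mu - b$mu) / b$mu, 0.02)
  expect_lt(abs(b2$sigma - b$sigma) / b$sigma, 0.02)
})

test_that("background estimator handles constant images and rejects tiny input", {
  b <- estimate_background(matrix(7, 50, 50))
  expect_equal(b$sigma, 0)
  expect_equal(b$threshold, b$mu)
  expect_error(estimate_background(matrix(1:9, 3, 3)), "1000")
})

test_that("G factor calibration nulls an isotropic solution", {
  eq <- polar_pair(matrix(10, 40, 40), matrix(10, 40, 40))
  expect_equal(g_factor_from_isotropic(eq), 1)
  skew <- polar_pair(matrix(10, 40, 40), matrix(20, 40, 40))
  G <- g_factor_from_isotropic(skew)
  expect_equal(G, 0.5)
  corrected <- polar_pair(skew$parallel, skew$perpendicular, g_factor = G)
  am <- anisotropy(corrected, bg = NULL, prefilter = FALSE)
  expect_equal(max(abs(am$r)), 0, tolerance = 1e-12)
  dark <- polar_pair(matrix(1, 40, 40), matrix(0, 40, 40))
  expect_error(g_factor_from_isotropic(dark), "perpendicular")
})

test_that("G-corrected pair rendered with the same G recovers the scene", {
  sc <- make_ea_scene(scene_spec(theta_d = 30))
  G <- 1.3
  pair <- polar_pair(sc$pair$parallel, sc$pair$perpendicular / G,
                     g_factor = G)
  am <- anisotropy(pair, bg = NULL, prefilter = FALSE)
  truth <- sc$truth$r
  sel <- is.finite(truth) & am$valid
  expect_lt(max(abs(am$r[sel] - truth[sel])), 1e-10)
})

test_that("region SNR is the mean over background sd, kept at exactly 5", {
  bg <- structure(list(mu = 0, sigma = 2, threshold = 6, mask = NULL),
                  class = "background_model")
  expect_equal(region_snr(rep(10, 20), bg), 5)
  expect_equal(region_snr(rep(9.9, 20), bg), 4.95)
  bg0 <- structure(list(mu = 0, sigma = 0, threshold = 0, mask = NULL),
                   class = "background_model")
  expect_warning(s <- region_snr(rep(1, 5), bg0), "infinite")
  expect_identical(s, Inf)
  expect_error(region_snr(numeric(0), bg), "empty")
})

test_that("SNR exclusion count matches a brute-force region scan", {
  set.seed(3)
  bg <- estimate_background(matrix(rnorm(4000, 0, 2), 50, 80))
  regions <- lapply(1:30, function(i) rnorm(50, mean = runif(1, 0, 20), sd = 1))
  snrs <- vapply(regions, region_snr, numeric(1), bg = bg)
  brute <- vapply(regions, function(v) mean(v) / bg$sigma, numeric(1))
  expect_equal(snrs, brute)
  expect_equal(sum(snrs < 5), sum(brute < 5))
})

test_that("four-channel inversion matches the forward model exactly", {
  qp <- quad_polarization(3, 2, 1, 2)
  expect_equal(qp$p, 0.5)
  expect_equal(qp$theta_deg, 0)
  # exhaustive round trip over the (p, theta) grid
  worst <- 0
  for (p in seq(0.1, 0.9, by = 0.1)) for (th in seq(0, 175, by = 5)) {
    I <- 2.5 * (1 + p * cos(2 * (c(0, 45, 90, 135) - th) * pi / 180))
    out <- quad_polarization(I[1], I[2], I[3], I[4])
    worst <- max(worst, abs(out$p - p), circ_dist180(out$theta_deg, th))
  }
  expect_lt(worst, 1e-10)
})

test_that("isotropic and degenerate four-channel inputs are flagged", {
  iso <- quad_polarization(2, 2, 2, 2)
  expect_true(iso$isotropic)
  expect_true(is.na(iso$theta_deg))
  expect_equal(iso$p, 0)
  expect_error(quad_polarization(0, 0, 0, 0), "total")
  # full polarization at the 45-degree analyzer
  full <- quad_polarization(1, 2, 1, 0)
  expect_equal(full$theta_deg, 45)
  expect_equal(full$p, 1)
})

test_that("four-channel inversion is invariant under the dipole dyad flip", {
  for (th in c(10, 80, 150)) {
    I1 <- 2.5 * (1 + 0.6 * cos(2 * (c(0, 45, 90, 135) - th) * pi / 180))
    I2 <- 2.5 * (1 + 0.6 * cos(2 * (c(0, 45, 90, 135) - th - 180) * pi / 180))
    a <- quad_polarization(I1[1], I1[2], I1[3], I1[4])
    b <- quad_polarization(I2[1], I2[2], I2[3], I2[4])
    expect_equal(a$theta_deg, b$theta_deg, tolerance = 1e-10)
    expect_equal(a$p, b$p, tolerance = 1e-10)
  }
})

test_that("quad calibration divides throughput and is idempotent at identity", {
  st <- array(runif(16 * 16 * 2, 1, 10), c(16, 16, 2))
  q <- quad_stack(st, 2 * st, st, st, throughput = c(1, 2, 1, 1))
  cal <- quad_calibrate(q)
  expect_equal(cal$I45, st)
  expect_equal(cal$I0, st)
  # identity calibration applied twice equals applied once
  cal2 <- quad_calibrate(cal)
  expect_equal(cal2$I0, cal$I0)
  expect_equal(cal2$I135, cal$I135)
})

test_that("quad calibration subtracts the cell-center background square", {
  base <- array(5, c(20, 20, 1))
  q <- quad_stack(base + 1, base + 2, base + 3, base + 4)
  cal <- quad_calibrate(q, cell_center = c(10, 10))
  expect_equal(max(abs(cal$I0)), 0)
  expect_equal(max(abs(cal$I135)), 0)
})

test_that("anisotropy-intensity diagnostic detects an injected slope", {
  set.seed(9)
  n <- 60
  inten <- matrix(runif(n * n, 100, 1000), n, n)
  # intensity-independent anisotropy
  r0 <- 0.2
  par <- inten * (1 + 2 * r0) / 3; perp <- inten * (1 - r0) / 3
  am <- anisotropy(polar_pair(par, perp), bg = NULL, prefilter = FALSE)
  d0 <- anisotropy_intensity_diagnostic(am)
  expect_lt(abs(d0$slope), 1e-12)
  # ramp r with intensity
  r1 <- 0.1 + 1e-4 * inten
  par <- inten * (1 + 2 * r1) / 3; perp <- inten * (1 - r1) / 3
  am1 <- anisotropy(polar_pair(par, perp), bg = NULL, prefilter = FALSE)
  d1 <- anisotropy_intensity_diagnostic(am1)
  expect_equal(d1$slope, 1e-4, tolerance = 1e-6)
  expect_gt(d1$correlation, 0.99)
  # empty mask violates the precondition
  expect_error(anisotropy_intensity_diagnostic(am1, mask = matrix(FALSE, n, n)),
               "100")
})
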