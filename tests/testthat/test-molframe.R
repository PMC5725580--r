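random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

test_that("frame construction meets its anchor-point invariants", {
  fr <- build_frame(c(0, 0, 0), c(1, 0, 0), c(0, 0, 1))
  expect_equal(fr$R, diag(3), ignore_attr = TRUE)
  set.seed(7)
  lig <- rnorm(3); alp <- rnorm(3); bet <- rnorm(3)
  fr2 <- build_frame(lig, alp, bet)
  expect_equal(apply_frame(fr2, lig), c(0, 0, 0))
  a2 <- apply_frame(fr2, alp)
  expect_gt(a2[1], 0)
  expect_lt(max(abs(a2[2:3])), 1e-9)
  b2 <- apply_frame(fr2, bet)
  expect_lt(abs(b2[2]), 1e-9)
  expect_gt(b2[3], 0)
  expect_error(build_frame(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), "collinear")
})

test_that("the frame removes any rigid pre-motion of the structure", {
  set.seed(8)
  pts <- matrix(rnorm(30), 10, 3)
  anchors <- pts[1:3, ]
  fr <- build_frame(anchors[1, ], anchors[2, ], anchors[3, ])
  framed <- apply_frame(fr, pts)
  for (k in 1:5) {
    R <- random_rotation(); t <- rnorm(3)
    moved <- sweep(pts %*% t(R), 2, t, "+")
    fr2 <- build_frame(moved[1, ], moved[2, ], moved[3, ])
    expect_equal(apply_frame(fr2, moved), framed, tolerance = 1e-9)
  }
  # frame idempotence: re-deriving the frame from framed coordinates gives
  # the identity
  fr3 <- build_frame(framed[1, ], framed[2, ], framed[3, ])
  expect_equal(fr3$R, diag(3), ignore_attr = TRUE, tolerance = 1e-9)
  expect_equal(fr3$origin, c(0, 0, 0), tolerance = 1e-9)
  # swapped junction points give a detectably different frame
  fr_sw <- build_frame(anchors[1, ], anchors[3, ], anchors[2, ])
  expect_gt(max(abs(fr_sw$R - fr$R)), 1e-3)
})

test_that("GFP dipole axis from slope and from atoms agree", {
  v <- gfp_dipole_axis()
  expect_equal(sqrt(sum(v^2)), 1)
  expect_equal(v, c(-0.026, 0.871, 0.439) / sqrt(sum(c(-0.026, 0.871, 0.439)^2)))
  # synthetic coordinates built from the same slope
  atoms <- tibble::tibble(
    resno = c(112, 146, 147), elety = c("N", "C", "O"),
    x = c(0, 2 * v[1] + 0.3, 2 * v[1] - 0.3),
    y = c(0, 2 * v[2] + 0.1, 2 * v[2] - 0.1),
    z = c(0, 2 * v[3] - 0.2, 2 * v[3] + 0.2))
  v2 <- gfp_dipole_axis(atoms)
  expect_lt(acos(pmin(1, abs(sum(v * v2)))) * 180 / pi, 1e-6)
  # vertical-axis toy case
  atoms3 <- tibble::tibble(resno = c(112, 146, 147), elety = c("N", "C", "O"),
                           x = c(0, 0, 0), y = c(0, 1, 1), z = c(0, 0, 0))
  expect_equal(gfp_dipole_axis(atoms3), c(0, 1, 0))
  expect_error(gfp_dipole_axis(atoms3[1:2, ]), "147")
})

test_that("orientation states rotate as specified", {
  d <- c(0, 0, 1)
  expect_equal(orient_dipoles(d, theta = 0, phi = 90), d)
  out <- orient_dipoles(d, theta = 0, phi = 45)
  expect_equal(out, c(sin(pi / 4), 0, cos(pi / 4)))
  # a dipole along y is fixed by any phi tilt at theta = 0
  expect_equal(orient_dipoles(c(0, 1, 0), theta = 0, phi = 23), c(0, 1, 0))
})

test_that("projection drops z and folds the in-plane angle", {
  expect_equal(project_dipole(c(0, 1, 0))$angle_deg, 90)
  expect_equal(project_dipole(c(1, 1, 0) / sqrt(2))$magnitude, 1)
  pr <- project_dipole(c(0.5, 0.5, 0.707))
  expect_equal(pr$angle_deg, 45)
  expect_equal(pr$magnitude, sqrt(0.5))
  ax <- project_dipole(c(0, 0, 1))
  expect_true(ax$axial)
  expect_true(is.na(ax$angle_deg))
})

test_that("ensemble dipole hits the coherent and cancelling closed forms", {
  coh <- dipole_ensemble(matrix(rep(c(cos(pi / 5), sin(pi / 5), 0), 10),
                                10, 3, byrow = TRUE))
  ed <- ensemble_dipole(coh, select_frac = 1)
  expect_equal(ed$p_ens, 1, tolerance = 1e-12)
  expect_equal(ed$theta_ens, 36, tolerance = 1e-9)
  orth <- dipole_ensemble(rbind(c(1, 0, 0), c(0, 1, 0)))
  ed0 <- ensemble_dipole(orth, select_frac = 1)
  expect_equal(ed0$p_ens, 0, tolerance = 1e-12)
  expect_true(ed0$isotropic)
  # negating all dipoles changes nothing (dyad symmetry)
  ed_neg <- ensemble_dipole(dipole_ensemble(-coh$vectors), select_frac = 1)
  expect_equal(ed_neg$theta_ens, ed$theta_ens)
  expect_error(ensemble_dipole(rbind(c(0, 0, 1))), "axial")
})

test_that("ensemble dipole matches the Monte-Carlo oracle", {
  set.seed(12)
  psi <- 95 + rnorm(400, 0, 10)
  vec <- cbind(cos(psi * pi / 180), sin(psi * pi / 180), 0)
  ed <- ensemble_dipole(dipole_ensemble(vec), select_frac = 1)
  expect_lt(circ_dist180(ed$theta_ens, 95), 1)
  expect_equal(ed$p_ens, mc_p_oracle(psi), tolerance = 1e-10)
  # p decreases monotonically with angular spread
  ps <- vapply(c(5, 15, 30, 50), function(s) {
    set.seed(13)
    psi <- 95 + rnorm(400, 0, s)
    v <- cbind(cos(psi * pi / 180), sin(psi * pi / 180), 0)
    ensemble_dipole(dipole_ensemble(v), select_frac = 1)$p_ens
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("energy selection keeps the stable lowest 40%", {
  vec <- matrix(rep(c(1, 0, 0), 10), 10, 3, byrow = TRUE)
  ens <- dipole_ensemble(vec, energy = c(5, 1, 3, 1, 2, 9, 1, 8, 7, 6))
  sel <- select_lowest_energy(ens, 0.4)
  expect_equal(nrow(sel$vectors), 4)
  # ties at energy 1 resolve in input order: members 2, 4, 7 then energy 2
  expect_equal(sort(sel$energy), c(1, 1, 1, 2))
})

test_that("global rigid motion leaves theta_ens, p_ens and the scan unchanged", {
  set.seed(14)
  pts <- matrix(rnorm(30), 10, 3)
  dip_local <- c(0.2, 0.9, 0.4); dip_local <- dip_local / sqrt(sum(dip_local^2))
  run <- function(P) {
    fr <- build_frame(P[1, ], P[2, ], P[3, ])
    # dipole is rigid with the structure: rotate it by the same motion
    ens <- dipole_ensemble(rbind(apply_frame(fr, attr(P, "dip"), vector = TRUE)))
    tilt_scan(ens, 95.4, 10.1, select_frac = 1)
  }
  attr(pts, "dip") <- dip_local
  base <- run(pts)
  R <- random_rotation()
  moved <- pts %*% t(R)
  attr(moved, "dip") <- as.numeric(dip_local %*% t(R))
  alt <- run(moved)
  expect_equal(base$theta_ens, alt$theta_ens, tolerance = 1e-9)
  expect_equal(base$p_ens, alt$p_ens, tolerance = 1e-9)
  expect_equal(base$consistent, alt$consistent)
})

test_that("tilt scan applies the circular one-sigma acceptance band", {
  # dipoles along y: theta_ens = 90 at every phi
  ens <- dipole_ensemble(matrix(rep(c(0, 1, 0), 8), 8, 3, byrow = TRUE))
  ts <- tilt_scan(ens, 95.4, 10.1)
  expect_equal(ts$phi, c(11.25, 22.5, 45, 67.5))
  expect_true(all(ts$consistent))
  expect_equal(ts$theta_ens, rep(90, 4))
  # zero-width band with a mismatch: nothing consistent
  ts0 <- tilt_scan(ens, 120, 0)
  expect_false(any(ts0$consistent))
  # wraparound: 2 versus 178 with sd 5 is consistent (distance 4)
  ens_x <- dipole_ensemble(matrix(rep(c(cos(2 * pi / 180),
                                        sin(2 * pi / 180), 0), 4),
                                  4, 3, byrow = TRUE))
  ts_w <- tilt_scan(ens_x, 178, 5, phi_grid = 90)
  expect_equal(ts_w$distance_deg, 4, tolerance = 1e-9)
  expect_true(ts_w$consistent)
})

test_that("PDB and ensemble-CSV readers round-trip fixture files", {
  pdb <- tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL        1",
    "ATOM      1  N   VAL A 112      1.000   2.000   3.000  1.00  0.00           N",
    "ATOM      2  C   ASN A 146      4.000   5.500   6.000  1.00  0.00           C",
    "ATOM      3  O   SER A 147      4.200   5.700   6.400  1.00  0.00           O",
    "ENDMDL",
    "END"), pdb)
  atoms <- read_pdb_atoms(pdb)
  expect_equal(nrow(atoms), 3)
  expect_equal(atoms$x, c(1, 4, 4.2))
  v <- gfp_dipole_axis(atoms)
  mid <- c(4.1, 5.6, 6.2) - c(1, 2, 3)
  expect_equal(v, mid / sqrt(sum(mid^2)))
  csv <- tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(dx = c(1, 0), dy = c(0, 2), dz = c(0, 0),
                                  energy = c(0.5, 0.1)), csv)
  ens <- read_ensemble_csv(csv)
  expect_equal(ens$vectors, rbind(c(1, 0, 0), c(0, 1, 0)))
  expect_equal(ens$energy, c(0.5, 0.1))
})
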