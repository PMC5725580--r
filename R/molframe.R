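# Molecular reference frame: placing atomic coordinates and transition
# dipole ensembles in microscope coordinates, rotating in (theta, phi),
# projecting to the image plane, and scanning tilts against a measured
# dipole-angle band.

normalize3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps) abort("zero-length vector")
  v / n
}

#' Dipole ensemble with energies
#'
#' A set of unit transition-dipole vectors with per-member energy scores.
#' The conventional selection rule keeps the lowest 40% of members by
#' energy; ties at the cutoff are resolved by input order (stable
#' selection).
#'
#' @param vectors n x 3 matrix of dipole vectors (normalized internally).
#' @param energy numeric length-n energy scores (lower = better); defaults
#'   to zeros.
#' @return object of class `dipole_ensemble`.
#' @export
dipole_ensemble <- function(vectors, energy = NULL) {
  vectors <- rbind(vectors)
  if (ncol(vectors) != 3L) abort("vectors must be n x 3")
  n <- sqrt(rowSums(vectors^2))
  if (any(n < .Machine$double.eps)) abort("zero-length dipole vector")
  vectors <- vectors / n
  if (is.null(energy)) energy <- rep(0, nrow(vectors))
  if (length(energy) != nrow(vectors))
    abort("energy must match the number of vectors")
  structure(list(vectors = unname(vectors), energy = as.numeric(energy)),
            class = "dipole_ensemble")
}

#' @export
print.dipole_ensemble <- function(x, ...) {
  cat(sprintf("<dipole_ensemble> %d members, energy range [%.3g, %.3g]\n",
              nrow(x$vectors), min(x$energy), max(x$energy)))
  invisible(x)
}

#' Select the lowest-energy fraction of an ensemble
#'
#' @param ens a [dipole_ensemble].
#' @param frac fraction kept (default 0.4, the lowest 40% by energy).
#' @return a `dipole_ensemble` with `ceiling(frac * n)` members; ordering
#'   among ties follows input order.
#' @export
select_lowest_energy <- function(ens, frac = 0.4) {
  stopifnot(inherits(ens, "dipole_ensemble"))
  n_keep <- max(1L, ceiling(frac * nrow(ens$vectors)))
  ord <- order(ens$energy)          # stable for ties
  keep <- sort(ord[seq_len(n_keep)])
  dipole_ensemble(ens$vectors[keep, , drop = FALSE], ens$energy[keep])
}

#' Build the integrin-microscope molecular reference frame
#'
#' Constructs the rigid transform that places atomic coordinates in the
#' frame in which: the ligand-point C-alpha is the origin; the X axis runs
#' through the alpha-junction C-alpha; and the beta-junction C-alpha lies
#' in the XZ half-plane with z > 0. The XY plane of this frame is parallel
#' to the microscope image plane (and the plasma membrane of a cell
#' adhering through the integrin). For LFA-1 the conventional anchors are
#' the internal-ligand Glu C-alpha, Arg-588 in the alpha-L subunit
#' (alpha-junction), and Pro-104 in beta-2 (beta-junction).
#'
#' @param ligand_pt,alpha_junction,beta_junction length-3 coordinates.
#' @return object of class `mol_frame`: rotation matrix `R` (rows = frame
#'   axes) and `origin`, applied as `R %*% (x - origin)`.
#' @export
build_frame <- function(ligand_pt, alpha_junction, beta_junction) {
  x_axis <- normalize3(alpha_junction - ligand_pt)
  v <- beta_junction - ligand_pt
  z_raw <- v - sum(v * x_axis) * x_axis
  if (sqrt(sum(z_raw^2)) < 1e-9 * sqrt(sum(v^2)))
    abort("the three anchor points are collinear")
  z_axis <- normalize3(z_raw)
  y_axis <- c(z_axis[2] * x_axis[3] - z_axis[3] * x_axis[2],
              z_axis[3] * x_axis[1] - z_axis[1] * x_axis[3],
              z_axis[1] * x_axis[2] - z_axis[2] * x_axis[1])  # z cross x
  structure(list(R = rbind(x = x_axis, y = y_axis, z = z_axis),
                 origin = as.numeric(ligand_pt)),
            class = "mol_frame")
}

#' @export
print.mol_frame <- function(x, ...) {
  cat("<mol_frame> rotation:\n"); print(round(x$R, 4))
  cat("origin:", format(x$origin, digits = 4), "\n")
  invisible(x)
}

#' Apply a molecular frame to coordinates or vectors
#'
#' @param frame a [build_frame] result.
#' @param coords n x 3 matrix or length-3 vector.
#' @param vector logical: if TRUE the translation is skipped (appropriate
#'   for direction vectors such as dipoles).
#' @return transformed coordinates, same shape.
#' @export
apply_frame <- function(frame, coords, vector = FALSE) {
  one <- is.null(dim(coords))
  coords <- rbind(coords)
  if (!vector) coords <- sweep(coords, 2, frame$origin)
  out <- coords %*% t(frame$R)
  if (one) as.numeric(out) else unname(out)
}

#' GFP transition dipole axis
#'
#' Returns the unit transition-dipole axis of GFP either from the published
#' slope of the dipole line in the 1w7s chain-B coordinate system
#' (x = -0.026, y = 0.871, z = 0.439) or from atomic coordinates, as the
#' line through the Val-112 backbone N atom and the midpoint of the
#' Asn-146 C and Ser-147 O atoms (1w7s numbering). The sign convention
#' fixes a positive y component (the dipole is an axis; the sign is a
#' bookkeeping choice).
#'
#' @param atoms optional tibble/data.frame of atom records with columns
#'   `resno`, `elety`, `x`, `y`, `z` (e.g. from [read_pdb_atoms]).
#' @param slope optional length-3 slope vector; the default is the
#'   published 1w7s chain-B value, used when `atoms` is `NULL`.
#' @return unit length-3 vector.
#' @export
gfp_dipole_axis <- function(atoms = NULL, slope = c(-0.026, 0.871, 0.439)) {
  if (is.null(atoms)) {
    v <- normalize3(slope)
  } else {
    pick <- function(resno, elety) {
      sel <- atoms$resno == resno & trimws(atoms$elety) == elety
      if (!any(sel))
        abort(sprintf("atom %s of residue %d not found", elety, resno))
      as.numeric(c(atoms$x[sel][1], atoms$y[sel][1], atoms$z[sel][1]))
    }
    n112 <- pick(112, "N")
    mid <- (pick(146, "C") + pick(147, "O")) / 2
    v <- normalize3(mid - n112)
  }
  if (v[2] < 0) v <- -v
  v
}

#' Orientation state of the molecule in the microscope frame
#'
#' The reference state is `theta = 0`, `phi = 90` (the molecule's X axis in
#' the image plane, untilted) and leaves coordinates unchanged. A tilt in
#' `phi` is a rotation about the Y axis by `90 - phi` degrees, which keeps
#' the alpha-junction in the XZ plane (the plane the molecule stays close
#' to when tilted by cytoskeletal force); `theta` is a subsequent rotation
#' about Z.
#'
#' @param dipoles n x 3 matrix or length-3 vector of unit dipoles (or a
#'   [dipole_ensemble]).
#' @param theta,phi orientation angles, degrees.
#' @return rotated dipoles, same shape/class as the input.
#' @export
orient_dipoles <- function(dipoles, theta = 0, phi = 90) {
  beta <- (90 - phi) * pi / 180
  Ry <- matrix(c(cos(beta), 0, sin(beta),
                 0, 1, 0,
                 -sin(beta), 0, cos(beta)), 3, 3, byrow = TRUE)
  th <- theta * pi / 180
  Rz <- matrix(c(cos(th), -sin(th), 0,
                 sin(th), cos(th), 0,
                 0, 0, 1), 3, 3, byrow = TRUE)
  R <- Rz %*% Ry
  if (inherits(dipoles, "dipole_ensemble")) {
    out <- dipoles
    out$vectors <- dipoles$vectors %*% t(R)
    return(out)
  }
  one <- is.null(dim(dipoles))
  out <- rbind(dipoles) %*% t(R)
  if (one) as.numeric(out) else unname(out)
}

#' Project a 3D dipole onto the image plane
#'
#' Drops the z component; the in-plane angle is the folded `atan2(y, x)`
#' and the in-plane magnitude is `sqrt(x^2 + y^2)`. A purely axial vector
#' has an undefined angle and is flagged.
#'
#' @param v length-3 vector or n x 3 matrix.
#' @return tibble with `angle_deg` (`[0,180)`, NA when axial),
#'   `magnitude`, `axial` flag.
#' @export
project_dipole <- function(v) {
  v <- rbind(v)
  if (any(rowSums(v^2) < .Machine$double.eps^2)) abort("zero vector")
  mag <- unname(sqrt(v[, 1]^2 + v[, 2]^2))
  axial <- unname(mag < 1e-12)
  ang <- unname(fold180(atan2(v[, 2], v[, 1]) * 180 / pi))
  ang[axial] <- NA_real_
  tibble(angle_deg = ang, magnitude = mag, axial = axial)
}

#' Ensemble dipole orientation and polarization factor
#'
#' Simulates the four-channel polarized intensities each ensemble member
#' would produce, `I(alpha) proportional to m^2 cos^2(alpha - psi)` with
#' `m` the in-plane projection magnitude and `psi` the in-plane angle
#' (photoselection under isotropic in-plane excitation), sums the channels
#' over the selected (lowest-energy-fraction) members, and inverts the sums
#' with [quad_polarization] to give the apparent single-dipole orientation
#' `theta_ens` and polarization factor `p_ens`. A coherent ensemble (all
#' members parallel and in-plane) gives `p_ens = 1`; equal members at 0 and
#' 90 degrees cancel to `p_ens = 0`.
#'
#' @param ens a [dipole_ensemble] (or n x 3 matrix; energies then 0).
#' @param select_frac energy-selection fraction applied first (default 0.4;
#'   use 1 to keep all members).
#' @return tibble with `theta_ens`, `p_ens`, `n_members`, `isotropic` flag.
#' @export
ensemble_dipole <- function(ens, select_frac = 0.4) {
  if (!inherits(ens, "dipole_ensemble")) ens <- dipole_ensemble(ens)
  sel <- select_lowest_energy(ens, select_frac)
  pr <- project_dipole(sel$vectors)
  if (all(pr$axial)) abort("all ensemble members are axial (no in-plane component)")
  alphas <- c(0, 45, 90, 135)
  psi <- pr$angle_deg; m2 <- pr$magnitude^2
  keep <- !pr$axial
  sums <- vapply(alphas, function(a)
    sum(m2[keep] * cos((a - psi[keep]) * pi / 180)^2), numeric(1))
  qp <- quad_polarization(sums[1], sums[2], sums[3], sums[4])
  tibble(theta_ens = qp$theta_deg, p_ens = qp$p,
         n_members = nrow(sel$vectors), isotropic = qp$isotropic)
}

#' Tilt scan against a measured dipole-angle band
#'
#' For `theta = 0` and each tilt `phi` in the grid, rotates the ensemble,
#' projects it, computes the ensemble dipole, and flags the tilt as
#' consistent when the circular (period-180) distance between `theta_ens`
#' and the measured dipole angle is within one measured standard deviation.
#'
#' @param ens a [dipole_ensemble].
#' @param measured_theta_d,measured_sd measured angle and sd, degrees.
#' @param phi_grid tilts to scan, degrees (default 11.25, 22.5, 45, 67.5).
#' @param theta in-plane rotation applied with each tilt (default 0).
#' @param select_frac energy-selection fraction (default 0.4).
#' @return tibble of class `tilt_scan`: `phi`, `theta_ens`, `p_ens`,
#'   `distance_deg`, `consistent`.
#' @export
tilt_scan <- function(ens, measured_theta_d, measured_sd,
                      phi_grid = c(11.25, 22.5, 45, 67.5), theta = 0,
                      select_frac = 0.4) {
  if (length(phi_grid) == 0L) abort("phi_grid must be non-empty")
  rows <- purrr::map_dfr(phi_grid, function(phi) {
    rot <- orient_dipoles(ens, theta = theta, phi = phi)
    ed <- ensemble_dipole(rot, select_frac = select_frac)
    d <- circ_dist180(ed$theta_ens, measured_theta_d)
    tibble(phi = phi, theta_ens = ed$theta_ens, p_ens = ed$p_ens,
           distance_deg = d, consistent = is.finite(d) & d <= measured_sd)
  })
  class(rows) <- c("tilt_scan", class(rows))
  rows
}

#' Read ATOM records from a PDB file
#'
#' Minimal fixed-width reader for single- and multi-model PDB files,
#' returning one row per ATOM record. Sufficient for anchor-atom extraction
#' by chain/residue/atom name; it is not a general-purpose PDB parser.
#'
#' @param path PDB file path.
#' @return tibble with `model`, `chain`, `resno`, `resid`, `elety`,
#'   `x`, `y`, `z`.
#' @export
read_pdb_atoms <- function(path) {
  lines <- readLines(path)
  model <- 1L
  out <- vector("list", length(lines))
  j <- 0L
  for (ln in lines) {
    tag <- substr(ln, 1, 6)
    if (startsWith(tag, "MODEL")) {
      model <- suppressWarnings(as.integer(trimws(substr(ln, 7, 14))))
      if (is.na(model)) model <- 1L
    } else if (tag == "ATOM  " || tag == "HETATM") {
      j <- j + 1L
      out[[j]] <- tibble(
        model = model,
        chain = trimws(substr(ln, 22, 22)),
        resno = as.integer(trimws(substr(ln, 23, 26))),
        resid = trimws(substr(ln, 18, 20)),
        elety = trimws(substr(ln, 13, 16)),
        x = as.numeric(substr(ln, 31, 38)),
        y = as.numeric(substr(ln, 39, 46)),
        z = as.numeric(substr(ln, 47, 54)))
    }
  }
  if (j == 0L) abort("no ATOM records found")
  dplyr::bind_rows(out[seq_len(j)])
}

#' Read a dipole-ensemble CSV
#'
#' Expected columns: `dx`, `dy`, `dz` (dipole vector, normalized on read)
#' and `energy`.
#'
#' @param path CSV file path.
#' @return a [dipole_ensemble].
#' @export
read_ensemble_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("dx", "dy", "dz", "energy")
  if (!all(need %in% names(d)))
    abort(sprintf("ensemble CSV needs columns: %s", paste(need, collapse = ", ")))
  dipole_ensemble(as.matrix(d[, c("dx", "dy", "dz")]), d$energy)
}
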