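---
title: "Measuring molecular orientation at the leading edge: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring molecular orientation at the leading edge: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polorient)
```

## The physical model

A fluorophore absorbs and emits light preferentially along its transition
dipole. When the fluorophore is rigidly coupled to a membrane receptor,
the in-plane projection of that dipole reports the receptor's orientation,
modulo the dipole's twofold (dyad) symmetry: an orientation and its
180-degree rotation are indistinguishable, so every angle in this package
lives on `[0, 180)` and all angular comparisons use the circular distance
with period 180 (`circ_dist180()`).

Two readouts are implemented.

**Emission anisotropy** (`anisotropy()`): with linearly polarized
excitation, emission analyzed parallel and perpendicular to the excitation
axis gives

$$r = \frac{I_\parallel - I_\perp}{I_\parallel + 2 I_\perp},$$

with the perpendicular intensity counted twice because two of the three
emission planes are perpendicular to the parallel one. For nonnegative
inputs, $r \in [-0.5, 1]$. If a population of dipoles is aligned at angle
$\theta_d$ from the local membrane normal, and $\gamma$ denotes the
orientation of the membrane normal relative to the polarization axis, the
anisotropy follows

$$r(\gamma) = C + A\cos^2(\gamma - \theta_d),$$

where $A$ (the absolute amplitude of angular dependence) measures the
degree of alignment and $C$ the isotropic baseline.

**Four-channel polarization** (`quad_polarization()`): with isotropic
(circularly polarized) excitation and simultaneous analyzers at
$\alpha \in \{0, 45, 90, 135\}^\circ$, the channel intensities of a dipole
population follow the forward model

$$I(\alpha) = \frac{I_{tot}}{4}\bigl(1 + p\cos 2(\alpha - \theta)\bigr),$$

which inverts exactly to

$$p = \frac{\sqrt{(I_0-I_{90})^2 + (I_{45}-I_{135})^2}}
          {\tfrac12 (I_0+I_{45}+I_{90}+I_{135})},\qquad
  \theta = \tfrac12\,\mathrm{atan2}(I_{45}-I_{135},\, I_0-I_{90}).$$

A note on the $\theta$ convention: a two-analyzer identity written without
the $\tfrac12$ factor, or with the difference ratio inverted, is not
consistent with using the same differences as quadrature components of
$p$. The implementation uses the atan2 form above because it is the exact
algebraic inverse of the forward model — a property the test suite checks
over an exhaustive $(p, \theta)$ grid — and reports $\theta$ folded to
`[0, 180)`. Isotropic input ($p = 0$) leaves $\theta$ undefined and is
flagged rather than assigned an arbitrary angle; under noise $p$ can
exceed 1 and is then reported with a flag, never silently clipped.

## Angle conventions

Rasters are R matrices with rows = y increasing downward. All angles are
measured counter-clockwise in the conventional display orientation (y up),
through the single helper `raster_angle(dx, dy) = atan2(-dy, dx)` folded
to `[0, 180)`. Without one shared helper, the inverted row axis silently
flips the handedness of every "counter-clockwise" angle; every module —
orientation map, ROI tangents, dipole angles, flow directions — goes
through it.

## The orientation map

To compare anisotropy across pixels of an irregular cell, each pixel needs
a reproducible geometric orientation (`orientation_map()`): the cell mask
is smoothed by a morphological closure (radius 3 px), the Euclidean
distance to the background is computed for in-cell pixels, and the
central-difference gradient of this distance field gives the local "away
from the edge" direction; its folded display angle is the orientation. On
a circular cell this is the folded azimuth of the membrane normal, running
0–180° along the polarization axis.

Two numerical choices matter:

* Near the boundary the raw distance map takes only a few discrete values
  and central differences snap to axis directions. The distance field is
  therefore smoothed with a Gaussian of sigma 3 px (the same scale as the
  closure radius) before the gradient; on a disk fixture this keeps
  boundary-adjacent orientations within about 2 degrees of the true
  normal.
* On the medial-axis ridge the gradient vanishes and the orientation is
  undefined; such pixels are NA and excluded from fits rather than given
  an arbitrary value.

## The cos² fit

`cos2_fit()` bins orientations to the closest `bin_width` degrees (10 by
default, 15 supported) and fits $r = C + A\cos^2(\gamma-\theta_d)$. Since
$\cos^2 x = \tfrac12 + \tfrac12\cos 2x$, the model is *linear* in
$(1, \cos 2\gamma, \sin 2\gamma)$: the fit is closed-form weighted
harmonic regression with $A = 2\sqrt{a_1^2+a_2^2}$,
$\theta_d = \tfrac12\,\mathrm{atan2}(a_2, a_1)$. This removes any
dependence on nonlinear-optimizer initialization (the 90°-aliased local
optimum of a naive cos² least squares simply does not arise) and
guarantees $A \ge 0$ and $\theta_d \in [0, 180)$ by construction.

The default fits count-weighted bin means (`mode = "binned"`); fitting
all pixels against their snapped orientations is available as
`mode = "pixels"`. Bin means were chosen as the default because the
binning residuals of the pixel-level variant put a ceiling of about
R² ≈ 0.99 on even perfect data at 10° bins, whereas the ideal-image
validation (below) is designed to be exactly invertible. Degenerate fits
— amplitude below $10^{-4}$, or occupied bins spanning less than 90° — are
reported with a status code, not dropped.

`fourier_amplitude()` provides the independent cross-check: the running
average of $r$ over orientation (1° grid, 10° circular boxcar — the window
is a package choice, documented and configurable) is mean-subtracted and
Fourier-transformed; by the identity above, the first-harmonic magnitude
equals $A/2$. Grid cells with no data are filled by circular interpolation
and flagged via `interpolated_fraction`.

## Segmentation chain

`segment_cells()` seeds per-cell segmentation from the background mask
(pixels above the μ + 3σ threshold of `estimate_background()`), expands
seeds by a 5 px dilation to retain local contrast, and refines by
thresholding (default) or a compact Chan–Vese-style active contour
(`method = "active_contour"`; iterated region-mean reassignment with
morphological smoothing — provided behind a flag because its parameters
are a package choice, with the threshold path being the tested default).
Cleanup: closure radius 1 px, removal of objects under `min_area`, hole
filling. In movies, only cells consistently segmented in ≥ 5 frames
(tracked by frame-overlap within a spatiotemporal bounding box) are kept.

The background estimator fits a Gaussian to the left shoulder (bins at or
below the histogram peak) of the intensity histogram, using a two-pass
histogram so that bright foreground stretching the intensity range by
orders of magnitude cannot de-resolve the background peak, and a
count-weighted log-quadratic regression as the fit. Exactly constant
background (noiseless scenes) short-circuits to σ = 0. Degenerate
histograms raise an error rather than returning silent defaults.

Downstream masks: `edge_mask()` (cell minus its 10 px erosion; thinner
cells degenerate to the whole cell with a flag), `detect_protrusions()`
(positive frame-to-frame mask differences linked into spatiotemporal
components — 8-connected in space, adjacent in time, the package's
reading of a "4D bounding box" — kept at ≥ 2000 px accumulated area and
≥ 5 frames persistence), and `leading_edge_mask()` (edge band intersected
with the union-over-frames support of accepted protrusions; the union is
used so the leading edge covers the whole protruding arc, not only the
pixels added in one frame).

`boundary_rois()` tiles non-overlapping 1000 × 500 nm rectangles along the
boundary, long axis tangent to the membrane. The tangent is the principal
axis of boundary points within ± 500 nm of arc length (the ROI length
scale); the contour is first smoothed with a circular 9-point boxcar
(about one ROI length) so single-pixel staircase steps do not jitter the
tangents. Tiling starts at the contour point nearest `start_near` when
given (e.g. a protrusion centroid) and the leftover arc shorter than one
ROI is dropped; ROIs are assumed non-overlapping. Cell-body ROIs reuse
the same long-axis angles, displaced 1250 nm inward (> 1000 nm from the
edge) so segmentation orientation cannot differ between the populations.

## Four-channel pipeline

`quad_calibrate()` divides channels by throughput factors (measured on an
isotropic dye solution), registers the three non-reference quadrants onto
the reference (affine transforms from bead images, `register_channels()`),
and optionally subtracts a per-channel background from a 4 × 4 px square
at the cell center. Registration precedes background subtraction so
background statistics come from the final pixel grid. `segment_dipole()`
sums the four channels over each ROI, inverts the sums, and reports
$\theta_d = (\theta - \mathrm{normal}) \bmod 180$. `radial_histogram()`
bins $\theta_d$ in 15° wedges with intensity-weighted mean $p$ per wedge,
and fits a circular Gaussian by the moment (wrapped-normal) estimator on
doubled angles — the estimator is a package choice where only the model
family is conventional. The histogram is reflected to `[180, 360)` for
display, honoring the dyad symmetry.

## Actin flow

`lucas_kanade_flow()` solves the windowed brightness-constancy least
squares per pixel (15 × 15 px window, 2 pyramid levels, one warped
refinement pass per level — parameters logged in the result and chosen to
recover displacements up to a few px without bias on translation
fixtures). Confidence is the smallest structure-tensor eigenvalue;
ill-conditioned pixels are masked, so textureless input yields an empty
field rather than spurious zeros. `flow_by_segment()` vector-averages
velocity per ROI (mean of vectors, not of angles, to avoid wraparound
bias) and reports the angle to the membrane tangent on `[0, 180)`.
`kymograph_velocity()` shears the space–time image by candidate
velocities and maximizes the variance of column means (a Radon-style
criterion) with parabolic sub-sample refinement; a broad high plateau
around the peak separates genuine streaks from noise, which produces only
isolated single-candidate spikes — input without a dominant orientation
errors out.

## Molecular reference frame

`build_frame()` maps atomic coordinates into the frame defined by three
Cα anchors: ligand point at the origin, α-junction on +x, β-junction in
the xz half-plane with z > 0; the xy plane is then parallel to the image
plane and the plasma membrane. The frame removes any rigid pre-motion of
the structure, so all downstream quantities are invariant to how the
input coordinates happened to be oriented (a tested property).

`orient_dipoles()` realizes a tilt in φ as a rotation about the y axis by
(90° − φ), the choice that keeps the α-junction exactly in the xz plane —
the plane the molecule stays close to when tilted by cytoskeletal force —
with θ as a subsequent rotation about z; the reference state
(θ = 0, φ = 90°) is the identity. `ensemble_dipole()` simulates each
member's four-channel intensities as
$I(\alpha) \propto m^2\cos^2(\alpha - \psi)$ with $m, \psi$ the in-plane
projection magnitude and angle (photoselection under isotropic in-plane
excitation — an internal convention validated against the coherent
$p = 1$ and orthogonal-cancellation $p = 0$ closed forms and a Monte-Carlo
oracle), sums over the selected members, and inverts with the
four-channel formulas. Member selection keeps the lowest 40% by energy,
with ties resolved by input order (stable selection) and equal weights
within the selected set. `tilt_scan()` applies the circular one-sigma
acceptance band $|\theta_{ens} - \theta_d^{meas}|_{180} \le sd$ over a
tilt grid (default 11.25, 22.5, 45, 67.5°). The twofold dipole ambiguity
means a scan cannot distinguish θ from θ + 180°; angles are reported
mod 180 throughout.

## The synthetic-scene generator

`make_ea_scene()` / `make_quad_scene()` render cells (disk, or disk
growing a half-disk protrusion over frames so protrusion detection has a
positive signal) with per-pixel dipole fields tied to the local membrane
normal via the *same* `orientation_map()` the analysis uses — generation
and analysis share one geometry definition. Channels are rendered by
inverting the anisotropy identity at constant in-cell total intensity
(set at 1000 counts, far above the 4σ gate, so noiseless scenes exclude
no pixels), or by the four-channel forward model; Gaussian background
and/or Poisson shot noise are added per the spec, and all randomness is
seed-reproducible bit for bit.

For the ideal-image validation the orientation field is quantized to the
analysis bin width (default 10°) before the cosine is applied
(`orientation_bin` in `scene_spec()`), making the noiseless pipeline
exactly invertible: the fit returns R² = 1 and the generating amplitude
and phase to machine precision, and the validation runs with the 3 × 3
prefilter off, since that filter exists to suppress small-integer division
noise that ideal images do not contain. `make_flow_movie()` translates a
band-limited texture by exact periodic Fourier shifts, so brightness
constancy holds to machine precision; `radial_inflow_field()` constructs
a synthetic centripetal flow field directly for testing the
angle-to-tangent chain; `make_ensemble()` draws dipoles about a mean
direction with pseudo-energies correlated with angular deviation so the
energy-selection rule is exercisable.

What the generator deliberately does **not** emulate: evanescent-field
depth effects and high-NA depolarization mixing, photobleaching, camera
gain beyond Gaussian/Poisson noise, cell-to-cell shape variability, or
homo-FRET (only the linear r-versus-intensity diagnostic is provided).
Passing tests therefore demonstrate the correctness of the estimators and
geometry on data obeying the stated forward models — not robustness to
every artifact of real microscopy, and not the biological values
themselves, whose raw data are not bundled.

## Problem sizes and determinism

Test and validation scenes are 192 × 192 px at 109 nm/px (cell radius
60 px ≈ 6.5 µm), flow movies 128 × 128 px with 8–15 frames, ensembles of
a few hundred members — sizes at which every pipeline stage completes in
seconds while leaving non-trivial geometry (≈ 30 boundary ROIs per cell,
18 orientation bins). All operations are deterministic given inputs,
parameters and seeds; the file-based runner writes a manifest (parameters,
package version, input checksums) so identical runs produce byte-identical
outputs.

## Known limitations

* Absolute anisotropy values are instrument-dependent; analyses should
  rely on relative comparisons (amplitudes, contrasts), as the estimators
  here do.
* The orientation map is comparable across cells only for near-circular
  shapes; for polarized cells the phase θd is comparable only within a
  cell, while the amplitude A remains comparable across cells.
* Bead registration fits a full affine; with fewer than ~5 well-spread
  beads the rotation/scale terms are weakly constrained.
* The kymograph estimator assumes a single dominant flow component along
  the sampling line.
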