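# polorient

Molecular orientation analysis for polarized fluorescence microscopy of
migrating cells.

Integrins and other membrane receptors can adopt preferred orientations
relative to the leading edge of a migrating cell — for example when
cytoskeletal force aligns them with the direction of retrograde actin flow.
Polarized fluorescence microscopy reads this orientation out through the
transition dipole of a rigidly attached fluorophore (e.g. a constrained
GFP fusion): the polarization of emission encodes the dipole's in-plane
angle. `polorient` implements the full analysis chain for two such
modalities, the supporting cell-morphology segmentation, actin-flow
velocimetry, and the structural geometry that connects the measured dipole
angle back to the orientation of the protein on the cell surface. A
synthetic-scene generator with exact ground truth makes every stage
testable end to end without raw microscopy data.

## The measurements

**Emission anisotropy (two channels).** With polarized excitation and
parallel/perpendicular detection,

```
r = (I_par − I_perp) / (I_par + 2 I_perp),        −0.5 ≤ r ≤ 1
```

after G-factor correction (`G = mean(I_par)/mean(I_perp)` on an isotropic
dye solution), per-frame background subtraction (half-Gaussian fit to the
left shoulder of the intensity histogram, threshold μ + 3σ), a 3×3
intensity-weighted prefilter, and an intensity gate at 4 background
standard deviations. Regions with SNR = μ/σ_bg below 5 are excluded.

**Angular dependence.** Every in-cell pixel gets a geometric orientation γ
from the gradient of the distance transform of the (smoothed) cell mask —
on a circular cell, the folded azimuth of the membrane normal. Binned
(γ, r) data are fitted to

```
r = C + A cos²(γ − θd)
```

where `A` is the absolute amplitude of angular dependence (the degree of
dipole alignment) and `θd` the dipole angle from the membrane normal. The
model is linear in `(1, cos 2γ, sin 2γ)`, so the fit is closed-form
harmonic regression; a Fourier estimate (first-harmonic amplitude = A/2)
cross-checks it.

**Four-channel polarization (instantaneous).** With isotropic excitation
and simultaneous analyzers at 0/45/90/135°,

```
p = sqrt((I0−I90)² + (I45−I135)²) / (0.5 (I0+I45+I90+I135))
θ = ½ atan2(I45−I135, I0−I90)   (mod 180°)
```

computed from throughput-normalized, background-corrected channel sums
over 1000 × 500 nm boundary ROIs whose long axis is tangent to the
membrane; `θd = θ − normal` per ROI, summarized in 15° radial histograms
with a circular-Gaussian fit.

**Actin flow.** Lucas–Kanade optical flow (pyramidal, warped refinement)
and kymograph streak-slope velocimetry quantify flow speed and its angle
to the membrane tangent.

**Molecular frame.** Three conserved Cα anchors (ligand point,
α-junction, β-junction) define a Cartesian frame whose XY plane is the
image plane. Transition-dipole ensembles (e.g. from loop-modeling, lowest
40% by energy) are rotated in (θ, φ), projected, and converted into an
ensemble dipole orientation and polarization factor; a tilt scan flags
which tilts φ are consistent with a measured θd ± sd band.

## Worked example

```r
library(polorient)

# a noiseless ideal cell whose anisotropy follows r = 0.1 + 0.05 cos2(gamma - 45)
spec  <- scene_spec(theta_d = 45, amplitude_A = 0.05, baseline_C = 0.1)
scene <- make_ea_scene(spec)
run_ea_pipeline(scene$pair, prefilter = FALSE)
#> <ea_result> per-region cos^2 fits:
#>   region   C    A theta_d r_squared n_pixels snr status
#> 1   cell 0.1 0.05      45         1    11289 Inf     ok
#> 2   edge 0.1 0.05      45         1     3536 Inf     ok
```

The pipeline re-derives the generating baseline (C = 0.1), amplitude
(A = 0.05) and phase (θd = 45°) with R² = 1: the ideal-image loop is
exactly invertible.

```r
# four-channel scene: ordered dipoles at 95 deg from the membrane normal
# (wrapped-normal sd 10 deg) at the leading edge, disordered cell body
sc  <- make_quad_scene(scene_spec(theta_d = 95, theta_sd = 10, p = 0.7,
                                  p_body = 0.05, total_intensity = 2000,
                                  seed = 7))
run_quad_pipeline(sc$quad, cell_mask = sc$truth$mask[, , 1])
#> <quad_result> 80 ROIs (80 ok)
#>   cell_body: mean theta_d = 93.6 deg (sd 2.7), mean p = 0.132
#>   leading_edge: mean theta_d = 95.3 deg (sd 1.9), mean p = 0.656
```

The leading-edge ROIs recover the preset 95° offset and a polarization
factor well above the disordered cell body — the synthetic analogue of an
ordered receptor population at the leading edge.

Result tables are tibbles throughout; fitted objects support `tidy()`,
`glance()` and `autoplot()`.

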