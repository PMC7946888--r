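---
title: "3D microrheology with multiplane microscopy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{3D microrheology with multiplane microscopy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mprheo)
```

## The problem

Passive microrheology with optical tweezers infers the viscosity of a
fluid from the thermal motion of a single trapped micron-scale bead. The
motion is three dimensional, but most instruments only track the bead in
the lateral (x–y) image plane. When the bead is imaged simultaneously at
several focal planes — a diffraction grating tiling nine different object
depths onto one camera frame — the axial (z) coordinate becomes accessible
too, provided one can turn the set of differently defocused sub-images
into a nanometre-scale z estimate. `mprheo` implements that localisation
scheme, the microrheology analysis downstream of it, and simulators for
both the bead dynamics and the image formation so the whole chain can be
validated against known ground truth.

## Trapped-bead dynamics

An overdamped bead in a harmonic trap in a Newtonian fluid performs
Ornstein–Uhlenbeck motion independently along each axis. Two closed forms
anchor everything else:

* equilibrium variance (equipartition): $\langle x^2\rangle = k_BT/\kappa$,
* normalised position autocorrelation:
  $\mathrm{NPAF}(\tau) = e^{-\tau/\tau_c}$ with
  $\tau_c = 6\pi\eta r/\kappa$,

and $\mathrm{NMSD}(\tau) = 1 - \mathrm{NPAF}(\tau)$ for a stationary
series. `simulate_trajectory()` uses the *exact* discrete OU transition
$x_{t+\Delta t} = x_t e^{-\Delta t/\tau_c} +
\xi\sqrt{(k_BT/\kappa)(1-e^{-2\Delta t/\tau_c})}$,
not an Euler scheme, so the simulated statistics are unbiased at any frame
rate — relevant because at the 67 Hz camera rate used throughout, the
relaxation time of a typical trap is comparable to the frame interval.
Defaults: T = 294 K (room temperature; configurable),
$k_B = 1.380649\times10^{-23}$ J/K. Inertia, hydrodynamic memory and wall
corrections are deliberately out of scope: the Newtonian analysis below
assumes a pure exponential NPAF.

```{r}
p <- trap_parameters(kappa_x = 1e-7, kappa_y = 1e-7, kappa_z = 4e-8,
                     bead_radius = 3e-6, solvent_viscosity = 0.00095)
relaxation_time(p, "z")
```

## Synthetic multiplane image formation

`render_frame()` produces a 3×3 tile of sub-images, one per object plane
at $z_n = n\,\Delta z$, $n = -4\ldots+4$ (layout configurable — the
physical tile-to-plane arrangement depends on the grating pair). The bead
is modelled as a uniformly bright projected disk convolved with a Gaussian
blur of width
$\sigma(n) = \sqrt{\sigma_0^2 + (s\,|z - n\Delta z|)^2}$,
normalised to unit mass so the integrated signal is conserved under
defocus and only the peak contrast drops. Real transmission images of
large beads show diffraction rings; this deliberately simpler unimodal
model keeps the one property the localisation method requires — a
symmetric sharpness-versus-defocus curve peaking at focus — and nothing
else, so passing tests validate the estimator logic, not a full optical
theory. Shot noise is Poisson (the sharpness metric's $I^2 - I$ form
presumes photon counting); it can be switched off for oracle tests.

Defaults, chosen once as plausible for a 60× water-immersion transmission
setup with LED illumination: 64 px tiles at 0.1833 µm/px (11 µm camera
pixels), background 100 counts, peak contrast 400 counts,
$\Delta z = 0.88$ µm, $\sigma_0 = 0.25$ µm and blur slope $s = 0.35$
(an effective condenser-limited NA near 0.35: in-focus blur at the
Rayleigh scale and a geometric blur cone of the same aperture). With
these values the sharpness-versus-z curve is adequately sampled by the
0.88 µm plane spacing, which is the design condition the instrument's
plane spacing was chosen for.

## Axial localisation from sharpness

Per frame, the pipeline is: split the tiled image into planes
(`split_frame`), compute one pooled Otsu threshold (`otsu_threshold`) and
take the intensity centre of mass of the sharpest plane's thresholded
sub-image for x–y (`xy_centroid`); in parallel, subtract the per-tile
median background, take absolute values (`preprocess_for_sharpness`), and
evaluate the sharpness
$S = \sum(I^2 - I)/(\sum I)^2$ of every plane. Two axial estimates follow:

* **Centre of sharpness** $z_{CS} = \sum_n z_n S_n / \sum_n S_n$ — smooth
  but biased toward zero: nine planes undersample the sharpness function,
  so the gradient of $z_{CS}$ against true z is well below one.
* **Sharpest plane**
  $z_{SP} = z_{sharpest} - (z_{sharpest} - z_{2nd})/4$ — accurate on
  average but quantised: a staircase with exact steps of $\Delta z/2$.

The in-situ self-calibration regresses the staircase on the smooth
estimate during a sweep of the bead through z (stage scan for a fixed
bead; trap-waist adjustment for a trapped one) and uses the fitted slope
as a rescale factor: $z_{RCS} = g\,(z_{CS} - c) + b$. The final axial
coordinate needs no separate calibration sample and no knowledge of the
bead size.

Numerical choices, made where the design was genuinely open:

* **Otsu pooling**: one threshold over the pooled nine-plane histogram, so
  a strongly defocused plane cannot lose the bead entirely. Implemented as
  an exact integer-histogram maximiser of the inter-class variance; the
  test suite cross-checks it against EBImage's independent implementation.
* **x–y plane choice**: the sharpest plane's sub-image (best SNR). The
  instrument's own choice is not documented; this is configuration-free
  here because the alternatives differed by far less than the shot noise
  in our experiments.
* **Background**: per-tile median — robust while the bead occupies a
  minority of the tile.
* **Calibration fit**: ordinary least squares of $z_{SP}$ on
  median-centred $z_{CS}$, restricted to $|z_{SP}| \le 2\Delta z$ and to
  frames whose sharpest plane is interior ($|n| < 3$), approximating the
  instrument procedure's guard against non-linearity far from focus. A
  comparison against step-mean, transition-lattice, robust-regression and
  quantisation-deconvolution variants showed plain OLS to be the most
  accurate on synthetic scans, so the simplest estimator stayed.
* **Ties** in the sharpest-plane ranking break toward the mid-plane
  (deterministic; ties have probability zero with noise).
* **Plane-spacing characterisation** (`characterize_plane_spacing`): for
  each plane, the stage position maximising its sharpness, by a quadratic
  fit over a ±0.5 µm stage window around the discrete argmax (a 3-point
  parabola is visibly noise-limited at 50 nm stage steps); $\Delta z$ is
  the slope of peak position against plane index. Planes peaking at the
  scan edge are excluded with a warning.
* **Degenerate inputs** raise classed errors (constant images, empty
  foregrounds, zero sharpness, too-few calibration steps), never NaNs.

```{r, eval = FALSE}
cfg <- optical_config(bead_diameter = 3)          # poisson noise default
zs <- seq(-2, 2, by = 0.05)                       # 50 nm stage scan
frames <- render_zscan(zs, cfg, seed = 1)
tr <- track(frames, cfg, calibration = "self")
mean(abs(tr$track$z_rcs_um - zs)[abs(zs) <= 1])   # ~0.01 um
```

## Microrheology readout

From a 3D trajectory: equipartition stiffness
$\kappa_i = k_BT/\langle x_i^2\rangle$, trap-volume width
$\mathrm{FWHM}_i = 2\sqrt{2\ln 2}\,\sigma_i$ (Gaussian equilibrium
distribution assumed — robust at desk-scale sample counts, unlike
histogram peak-finding), and the correlation curves. NPAF uses the
all-pairs product estimator at logarithmically thinned lags, NMSD the
independent squared-increment estimator; both subtract the sample mean
(the trap centre is not known a priori) and default to a maximum lag of a
tenth of the record, bounding estimator variance. On the dimensionless
axis $\tau^* = \tau\kappa/(6\pi r\eta_s)$ the curves of all axes collapse
onto one master curve, and the first downward crossing of
$\mathrm{NPAF} = e^{-1}$ — located by linear interpolation in
log-$\tau^*$, where the near-exponential curve is near-linear — reads off
the relative viscosity $\eta_r = \eta/\eta_s$ directly. The
`allan_deviation()` diagnostic (overlapping estimator, octave-spaced
cluster times) decays for a drift-free record and turns upward under
instrumental drift.

```{r}
traj <- simulate_trajectory(p, frame_rate = 67, n_frames = 1e5, seed = 1)
rheology(traj, bead_radius = p$bead_radius,
         solvent_viscosity = p$solvent_viscosity)$table
```

## What the simulations do and do not establish

The synthetic generators emulate: anisotropic trapped Brownian motion at a
camera-limited frame rate, and defocus-blurred transmission images with
shot noise on a 3×3 multiplane tile. They do not emulate diffraction
rings, camera read noise, illumination gradients, exposure blur, sample
drift, or depth-dependent aberrations. Green test suites therefore
establish that the estimators are correct for the physics they model —
exact OU statistics in, correct κ, FWHM and η_r out; known bead position
in, faithful z_RCS out — not that the instrument-side systematics of real
data are negligible.

Problem sizes are chosen so the whole suite runs at a desk: 10⁵-frame
trajectories for the statistical readouts (the scale of a real
measurement), 81–161-frame rendered z-scans for the localisation
fixtures, 48 px tiles in unit tests and the full 64 px default in
end-to-end checks. Estimator-precision properties (κ recovery within 3%,
variance within 5%, the τ* master-curve collapse gap below 0.05) are
asserted on simulations whose relaxation times are short relative to the
record, so that the bound tests the estimator rather than the record's
effective sample count; at the water-measurement trap parameters the z
axis holds only ~550 effectively independent samples per 10⁵ frames, and
those bounds would be dominated by seed luck.

## Known limitations

* The self-calibration's offset precision is set by the ~9 staircase
  transitions an 81-frame sweep contains; on the 6 µm bead the central
  mean residual consequently scatters between ~10 and ~25 nm across noise
  realisations. Longer sweeps tighten it.
* Larger beads narrow the linear range of $z_{CS}$; with very weak traps
  a large bead can leave the linear region and bias z displacements low.
* The $e^{-1}$ readout is Newtonian-only; no viscoelastic moduli are
  extracted.
* Single-particle tracking only: no multi-bead segmentation or linking.
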