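# mprheo — 3D particle tracking and microrheology with multiplane microscopy

`mprheo` is an R toolkit for **passive microrheology with optical
tweezers in three dimensions**. It is aimed at experimentalists running a
multiplane imaging system — a pair of distorted diffraction gratings that
tile nine focal planes onto one camera frame — around an optical trap, and
at anyone who wants to study such a system in simulation before building
one. The package covers the full chain:

1. **Trapped-bead simulation** — exact Ornstein–Uhlenbeck dynamics of a
   bead in an anisotropic harmonic trap in a Newtonian fluid
   (`simulate_trajectory()`), with the analytic correlation functions as
   oracles (`analytic_npaf()`).
2. **Synthetic multiplane imaging** — tiled camera frames of a bead whose
   blur grows with defocus from each plane, with Poisson shot noise
   (`render_frame()`, `render_zscan()`, `render_trajectory_frames()`),
   providing ground truth for the tracker.
3. **3D localisation** (`track()`) — per frame: plane segmentation, pooled
   Otsu threshold, centre-of-mass x–y; per-plane image sharpness
   S = Σ(I² − I)/(ΣI)², combined into two axial estimates
   — the smooth, biased *centre of sharpness*
   z₍CS₎ = Σ zₙSₙ / ΣSₙ and the quantised *sharpest plane*
   z₍SP₎ = z₁ − (z₁ − z₂)/4 (a staircase with Δz/2 steps) — and an
   **in-situ self-calibration** that regresses the staircase on z₍CS₎ and
   rescales it into real micrometres: z₍RCS₎ = g·(z₍CS₎ − c) + b. No
   look-up table, no separate calibration sample, no knowledge of bead
   size needed. `characterize_plane_spacing()` measures Δz itself from a
   stage scan.
4. **Microrheology** (`rheology()`) — equipartition trap stiffness
   κ = k_BT/⟨x²⟩, trap-volume FWHM = 2√(2 ln 2)·σ, NMSD/NPAF correlation
   curves, and the fluid's **relative viscosity read directly off the
   curve**: on the dimensionless lag axis τ\* = τκ/(6πrη_s), the NPAF of a
   Newtonian fluid crosses e⁻¹ at τ\* = η/η_s. An Allan-deviation
   diagnostic (`allan_deviation()`) checks for instrumental drift.

## Worked example

Simulate a 100,000-frame measurement of a 6 µm bead in water at 67 Hz
(κ_x = κ_y ≈ 1e-7 N/m, κ_z ≈ 4e-8 N/m) and analyse it:

```r
library(mprheo)
p <- trap_parameters(kappa_x = 1e-7, kappa_y = 1e-7, kappa_z = 4e-8,
                     bead_radius = 3e-6, solvent_viscosity = 0.00095)
traj <- simulate_trajectory(p, frame_rate = 67, n_frames = 1e5, seed = 1)
rheology(traj, p$bead_radius, p$solvent_viscosity)
#> Microrheology result (r = 3e-06 m, eta_s = 0.00095 Pa s, T = 294.0 K):
#>  axis kappa_N_per_m variance_um2   fwhm_um     eta_r
#>     x  1.037097e-07   0.03913914 0.4658685 0.9894502
#>     y  1.003701e-07   0.04044142 0.4735556 1.0202847
#>     z  3.710097e-08   0.10940707 0.7788977 0.9919177
```

The recovered stiffnesses match the inputs; the trap volume is a prolate
spheroid (FWHM ≈ 0.47, 0.47, 0.78 µm — wider along the optical axis,
where the trap is weaker); and the relative viscosity is 1 on every axis,
as it must be for the pure solvent.

Localisation accuracy on synthetic frames with known truth — a 50 nm
z-scan of a fixed 3 µm bead through ±2 µm, tracked with the self-
calibrated pipeline:

```r
cfg <- optical_config(bead_diameter = 3)      # 0.88 um plane spacing
zs <- seq(-2, 2, by = 0.05)
tr <- track(render_zscan(zs, cfg, seed = 1), cfg, calibration = "self")
tr$calibration
#> Axial rescaling calibration: gradient 2.085, offset -0.01778 um (n = 69, z_SP in [-1.54, 1.54] um)
mean(abs(tr$track$z_rcs_um - zs)[abs(zs) <= 1])  # mean |z_RCS - z| [um]
#> [1] 0.0119...
```

Roughly 12 nm mean axial error over the ±1 µm region a trapped bead
actually explores. The gradient ~2.1 is the rescale factor that undoes
the centre-of-sharpness undersampling bias for this bead and illumination.

## Command line

A thin launcher wraps the same functions for shell use:

```sh
Rscript inst/cli/mprheo.R demo --seed 7 --outdir out/     # full synthetic chain
Rscript inst/cli/mprheo.R track --frames frames.tif --out track.csv
Rscript inst/cli/mprheo.R rheology --trajectory traj.csv --out results.csv
```

Subcommands: `simulate`, `render`, `plane-spacing`, `calibrate`, `track`,
`rheology`, `demo`. Frames travel as multi-page 16-bit TIFF, trajectories
and results as CSV with units in the column names, configuration as YAML;
every run writes its fully resolved configuration (seeds included) next to
its outputs. Exit codes: 0 success, 2 usage, 3 data/format, 4 numerical.

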