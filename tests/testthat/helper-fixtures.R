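# Shared fixtures: the water-measurement trap (3 um-radius bead, 67 Hz)
# and a fast-mixing trap whose relaxation time is shorter than one frame,
# for estimator-precision tests.

water_trap <- function(kappa_x = 1e-7, kappa_y = 1e-7, kappa_z = 4e-8,
                       bead_radius = 3e-6) {
  trap_parameters(kappa_x, kappa_y, kappa_z, temperature_K = 294,
                  bead_radius = bead_radius, solvent_viscosity = 0.00095)
}

fast_trap <- function(kappa = 1e-7) {
  # r = 0.1 um -> tau_c ~ 1.8e-2 s, well mixed at 67 Hz
  trap_parameters(kappa, kappa, kappa, temperature_K = 294,
                  bead_radius = 1e-7, solvent_viscosity = 0.00095)
}

# Small, fast optical configuration for unit tests (48 px tiles, 2 um bead)
small_config <- function(noise_model = "none", ...) {
  optical_config(tile_pixels = 48L, bead_diameter = 2,
                 noise_model = noise_model, ...)
}

# Anisotropic trap on a 2 um bead: same kappa_z/kappa_x ratio as the
# water measurement but relaxation times well inside the record length,
# so correlation-curve properties are limited by the estimator, not by
# the record's effective sample count.
collapse_trap <- function() {
  trap_parameters(1e-7, 1e-7, 4e-8, bead_radius = 1e-6,
                  solvent_viscosity = 0.00095)
}

# Trajectory wrapper around a bare numeric series (x axis; y, z zeros+noise
# would be degenerate, so all three axes get the series)
series_trajectory <- function(x, frame_rate = 67) {
  new_trajectory((seq_along(x) - 1) / frame_rate,
                 cbind(x = x, y = x, z = x), frame_rate = frame_rate)
}
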