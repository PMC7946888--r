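# Synthetic multiplane image formation.
#
# The bead is modelled as a uniformly bright projected disk of the bead
# diameter, convolved with an isotropic Gaussian blur whose width grows
# linearly with defocus from each object plane:
#   sigma(n) = sqrt(psf_sigma0^2 + (defocus_slope * |z - n dz|)^2).
# The kernel is normalised to unit mass, so the integrated signal above
# background is conserved across defocus and only the peak contrast falls
# as the blur grows -- the property the sharpness metric keys on. Real
# transmission images of large beads show diffraction rings; this simpler
# unimodal model preserves the feature the localisation method relies on
# (a symmetric sharpness-vs-defocus curve peaking at focus).

# Radial profile of a unit-mass disk of radius R convolved with a Gaussian
# of width sigma, evaluated at radii rho [um]. Uses the exponentially
# scaled Bessel I0 so the integrand never overflows.
blurred_disk_profile <- function(rho, R, sigma) {
  nu <- max(64L, min(600L, ceiling(4 * R / sigma)))
  u <- (seq_len(nu) - 0.5) * (R / nu)
  du <- R / nu
  arg <- outer(rho, u) / sigma^2                     # rho x u
  core <- exp(-(outer(rho, -u, `+`))^2 / (2 * sigma^2)) *
    besselI(arg, 0, expon.scaled = TRUE)
  as.numeric(core %*% (u * du / sigma^2)) / (pi * R^2)
}

# One sub-image (tile_pixels x tile_pixels, double) of a bead centred at
# (x, y) um seen from the plane at plane_z um; background not included.
render_subimage_signal <- function(x, y, z, plane_z, config) {
  R <- config$bead_diameter / 2
  sigma <- sqrt(config$psf_sigma0^2 +
                  (config$defocus_slope * abs(z - plane_z))^2)
  coords <- tile_coords(config)
  rho <- sqrt(outer((coords - y)^2, (coords - x)^2, `+`))  # rows = y
  rmax <- max(rho)
  knots <- seq(0, rmax + 1e-9, by = min(config$pixel_size, sigma) / 2)
  if (length(knots) < 8) knots <- seq(0, rmax + 1e-9, length.out = 8)
  prof <- blurred_disk_profile(knots, R, sigma)
  peak0 <- (1 - exp(-R^2 / (2 * config$psf_sigma0^2))) / (pi * R^2)
  amp <- config$contrast / peak0
  matrix(approx(knots, prof, xout = as.numeric(rho), rule = 2)$y * amp,
         nrow = config$tile_pixels)
}

#' Render one tiled multiplane camera frame of a bead
#'
#' Produces the synthetic analogue of a single camera exposure: a
#' `tile_shape` grid of sub-images, one per object plane, of a bead at a
#' known 3D position. See the package vignette for the image-formation
#' model.
#'
#' @param position Numeric `c(x, y, z)` bead position [um]; x and y are
#'   measured from the tile centre, z from the central object plane.
#' @param config An [optical_config()].
#' @param seed Optional integer seed for the shot noise; if `NULL` the
#'   current RNG state is used (so frame sequences are reproducible from a
#'   single upstream seed).
#' @param timestamp Time of the frame [s], recorded in the result.
#' @return A `raw_frame`: list with `image` (integer matrix,
#'   rows*tile_pixels x cols*tile_pixels), `timestamp`, and `truth`
#'   (the input position).
#' @export
render_frame <- function(position, config, seed = NULL, timestamp = 0) {
  stopifnot(inherits(config, "optical_config"))
  mp_check(length(position) == 3 && all(is.finite(position)),
           "mprheo_invalid_parameter", "position must be finite c(x, y, z)")
  half_extent <- config$tile_pixels * config$pixel_size / 2
  R <- config$bead_diameter / 2
  if (max(abs(position[1:2])) + R > half_extent)
    mp_stop("mprheo_domain_error",
            "bead at (%.3g, %.3g) um extends outside the %.3g um half-width tile",
            position[1], position[2], half_extent)
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- config$tile_pixels
  rows <- config$tile_shape[1]; cols <- config$tile_shape[2]
  img <- matrix(0, rows * n, cols * n)
  for (k in seq_len(config$n_planes)) {
    n_idx <- config$tile_layout[k]
    sub <- config$background_level +
      render_subimage_signal(position[1], position[2], position[3],
                             n_idx * config$plane_spacing, config)
    r0 <- ((k - 1) %/% cols) * n
    c0 <- ((k - 1) %% cols) * n
    img[r0 + seq_len(n), c0 + seq_len(n)] <- sub
  }
  img <- if (config$noise_model == "poisson") {
    matrix(rpois(length(img), lambda = img), nrow(img))
  } else {
    round(img)
  }
  storage.mode(img) <- "integer"
  structure(list(image = img, timestamp = timestamp,
                 truth = as.numeric(position)),
            class = "raw_frame")
}

#' Render frames for a whole trajectory
#'
#' One tiled frame per trajectory sample, with the ground-truth position
#' recorded in each frame.
#'
#' @param traj A `trajectory` (see [simulate_trajectory()]).
#' @param config An [optical_config()].
#' @param seed Integer seed governing the shot noise of the whole sequence.
#' @return A list of `raw_frame` objects.
#' @export
render_trajectory_frames <- function(traj, config, seed = 1L) {
  stopifnot(inherits(traj, "trajectory"))
  set.seed(as.integer(seed))
  lapply(seq_len(nrow(traj$positions)), function(i) {
    tryCatch(
      render_frame(traj$positions[i, ], config, seed = NULL,
                   timestamp = traj$times[i]),
      mprheo_domain_error = function(e) mp_stop(
        "mprheo_domain_error", "frame %d: %s", i, conditionMessage(e)))
  })
}

#' Render a z-scan of a fixed bead
#'
#' Emulates the stage-scan calibration experiment: a bead held fixed
#' laterally at the tile centre while the stage steps it through a set of
#' axial positions. Each frame's `truth` carries the stage z.
#'
#' @param z_positions Monotone vector of stage z positions [um].
#' @param config An [optical_config()].
#' @param seed Integer seed for the shot noise.
#' @return A list of `raw_frame` objects, one per stage position.
#' @export
render_zscan <- function(z_positions, config, seed = 1L) {
  mp_check(length(z_positions) >= 1 && all(is.finite(z_positions)),
           "mprheo_invalid_parameter", "z_positions must be finite")
  if (length(z_positions) > 1) {
    d <- diff(z_positions)
    mp_check(all(d > 0) || all(d < 0), "mprheo_invalid_parameter",
             "z_positions must be monotone")
  }
  set.seed(as.integer(seed))
  lapply(seq_along(z_positions), function(i)
    render_frame(c(0, 0, z_positions[i]), config, seed = NULL,
                 timestamp = i - 1))
}
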