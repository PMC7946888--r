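#' Optical configuration of the multiplane imaging system
#'
#' Describes how a single camera frame encodes several focal planes: a grid
#' of `tile_shape` sub-images, each `tile_pixels` wide, where the sub-image
#' at grid position k images the object plane at z = n_k * plane_spacing
#' (n_k from `tile_layout`). Also carries the parameters of the synthetic
#' image-formation model used by [render_frame()]: a bead rendered as a
#' projected disk convolved with a Gaussian blur whose width grows linearly
#' with defocus.
#'
#' @param plane_spacing Axial separation between adjacent imaged planes
#'   [um]. Default 0.88 um.
#' @param n_planes Number of planes (odd). Default 9.
#' @param tile_shape Integer c(rows, cols) of the sub-image grid. Default
#'   c(3, 3).
#' @param tile_layout Integer vector, length `n_planes`, giving the plane
#'   index n of each tile in row-major grid order; must be a permutation of
#'   -(n_planes-1)/2 ... +(n_planes-1)/2. Default `4:-4` (top-left tile is
#'   the deepest plane, decreasing row-major). The physical arrangement
#'   produced by a given grating pair is instrument-specific, hence
#'   configuration rather than a constant.
#' @param pixel_size Object-space pixel size [um/pixel]. Default 0.1833
#'   (11 um camera pixels behind a 60x objective).
#' @param tile_pixels Side length of each square sub-image [pixels].
#'   Default 64.
#' @param background_level Constant background [counts]. Default 100.
#' @param bead_diameter Bead diameter [um]. Default 3.
#' @param psf_sigma0 In-focus Gaussian blur width [um]. Default 0.25, about
#'   the Rayleigh resolution of green-LED transmission imaging at an
#'   effective (condenser-limited) NA near 0.35.
#' @param defocus_slope Growth of the blur width per micrometre of defocus
#'   [dimensionless]. Default 0.35, the geometric blur-cone slope for the
#'   same effective NA.
#' @param contrast Peak in-focus signal above background [counts].
#'   Default 400.
#' @param noise_model `"poisson"` (shot noise, default) or `"none"`.
#' @return An object of class `optical_config`.
#' @export
optical_config <- function(plane_spacing = 0.88,
                           n_planes = 9L,
                           tile_shape = c(3L, 3L),
                           tile_layout = NULL,
                           pixel_size = 0.1833,
                           tile_pixels = 64L,
                           background_level = 100,
                           bead_diameter = 3,
                           psf_sigma0 = 0.25,
                           defocus_slope = 0.35,
                           contrast = 400,
                           noise_model = c("poisson", "none")) {
  noise_model <- match.arg(noise_model)
  n_planes <- as.integer(n_planes)
  tile_shape <- as.integer(tile_shape)
  mp_check(is.finite(plane_spacing) && plane_spacing > 0,
           "mprheo_invalid_parameter", "plane_spacing must be positive")
  mp_check(n_planes %% 2L == 1L && n_planes >= 3L,
           "mprheo_invalid_parameter", "n_planes must be odd and >= 3")
  mp_check(length(tile_shape) == 2L && prod(tile_shape) == n_planes,
           "mprheo_invalid_parameter",
           "tile_shape must be c(rows, cols) with rows*cols == n_planes")
  half <- (n_planes - 1L) %/% 2L
  tile_layout <- as.integer(tile_layout %||% (half:(-half)))
  mp_check(setequal(tile_layout, -half:half) &&
             length(tile_layout) == n_planes,
           "mprheo_invalid_parameter",
           "tile_layout must be a permutation of %d:%d", -half, half)
  mp_check(pixel_size > 0 && tile_pixels >= 8, "mprheo_invalid_parameter",
           "pixel_size must be positive and tile_pixels >= 8")
  mp_check(background_level >= 0 && contrast > 0 && bead_diameter > 0 &&
             psf_sigma0 > 0 && defocus_slope > 0,
           "mprheo_invalid_parameter",
           "background_level must be >= 0; contrast, bead_diameter, psf_sigma0, defocus_slope must be > 0")
  structure(list(plane_spacing = plane_spacing, n_planes = n_planes,
                 tile_shape = tile_shape, tile_layout = tile_layout,
                 pixel_size = pixel_size, tile_pixels = as.integer(tile_pixels),
                 background_level = background_level,
                 bead_diameter = bead_diameter, psf_sigma0 = psf_sigma0,
                 defocus_slope = defocus_slope, contrast = contrast,
                 noise_model = noise_model),
            class = "optical_config")
}

#' @export
print.optical_config <- function(x, ...) {
  cat(sprintf(
    "Multiplane optical configuration: %d planes (%dx%d tiles of %d px), dz = %.3g um\n",
    x$n_planes, x$tile_shape[1], x$tile_shape[2], x$tile_pixels,
    x$plane_spacing))
  cat(sprintf("  pixel %.4g um; bead %.3g um; blur sigma0 %.3g um + %.3g/um; %s noise\n",
              x$pixel_size, x$bead_diameter, x$psf_sigma0, x$defocus_slope,
              x$noise_model))
  invisible(x)
}

plane_indices <- function(config) {
  half <- (config$n_planes - 1L) %/% 2L
  -half:half
}

# Pixel-centre coordinates of one tile [um], origin at the tile centre.
tile_coords <- function(config) {
  n <- config$tile_pixels
  (seq_len(n) - (n + 1) / 2) * config$pixel_size
}
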