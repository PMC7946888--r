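make_profile <- function(values, config = optical_config()) {
  idx <- -(length(values) - 1) / 2
  structure(list(values = values,
                 plane_index = seq(idx, -idx),
                 plane_z = seq(idx, -idx) * config$plane_spacing),
            class = "sharpness_profile")
}

test_that("frame splitting partitions the tiles losslessly", {
  cfg <- optical_config(noise_model = "poisson")
  fr <- render_frame(c(0.3, -0.2, 0.5), cfg, seed = 3)
  expect_identical(dim(fr$image), c(192L, 192L))
  st <- split_frame(fr, cfg)
  expect_identical(dim(st$sub_images), c(64L, 64L, 9L))
  expect_identical(assemble_frame(st, cfg), fr$image)

  # permuting the layout permutes which tile lands on which plane index
  perm <- optical_config(tile_layout = c(-4:4), noise_model = "poisson")
  st2 <- split_frame(fr$image, perm)
  expect_identical(st2$sub_images[, , match(4L, st2$plane_index)],
                   st$sub_images[, , match(-4L, st$plane_index)])

  expect_error(split_frame(matrix(0L, 100, 192), cfg),
               regexp = "192 x 192", class = "mprheo_format_error")
})

test_that("pooled Otsu threshold separates bead from background", {
  x <- matrix(c(rep(100L, 900), rep(500L, 100)), 100)
  th <- otsu_threshold(x)
  expect_true(th > 100 && th < 500)
  expect_equal(th, otsu_threshold(matrix(sample(as.integer(x)), 50)))
  expect_error(otsu_threshold(matrix(7L, 10, 10)),
               class = "mprheo_degenerate_data")

  # on a rendered frame, supra-threshold pixels of the sharpest plane all
  # lie within 1.5 bead radii of the true position
  cfg <- optical_config(noise_model = "none")
  st <- split_frame(render_frame(c(0.4, -0.3, 0), cfg), cfg)
  th2 <- otsu_threshold(st)
  sub <- st$sub_images[, , match(0L, st$plane_index)]
  coords <- (seq_len(64) - 32.5) * cfg$pixel_size
  rho <- sqrt(outer((coords + 0.3)^2, (coords - 0.4)^2, `+`))
  expect_true(all(rho[sub >= th2] <= 1.5 * cfg$bead_diameter / 2))
})

test_that("Otsu agrees with the independent EBImage implementation", {
  cfg <- optical_config(noise_model = "poisson")
  st <- split_frame(render_frame(c(0.1, 0.2, 0.4), cfg, seed = 11), cfg)
  x <- as.integer(st$sub_images)
  ours <- otsu_threshold(st)
  theirs <- EBImage::otsu(matrix(x, 64), range = range(x),
                          levels = diff(range(x)) + 1L)
  expect_lt(abs(ours - theirs), 1)
})

test_that("centre-of-mass x-y localisation is exact, equivariant, accurate", {
  cfg <- optical_config(noise_model = "none")
  st <- split_frame(render_frame(c(0, 0, 0), cfg), cfg)
  sub <- st$sub_images[, , match(0L, st$plane_index)]
  th <- otsu_threshold(st)
  expect_equal(unname(xy_centroid(sub, th, cfg)), c(0, 0), tolerance = 1e-9)

  shifted <- split_frame(render_frame(c(3 * cfg$pixel_size, 0, 0), cfg), cfg)
  xy <- xy_centroid(shifted$sub_images[, , 5], th, cfg)
  expect_equal(unname(xy[["x"]]), 3 * cfg$pixel_size, tolerance = 1e-6)
  expect_equal(unname(xy[["y"]]), 0, tolerance = 1e-9)

  st3 <- split_frame(render_frame(c(0.30, -0.20, 0), cfg), cfg)
  xy3 <- xy_centroid(st3$sub_images[, , 5], otsu_threshold(st3), cfg)
  expect_lt(abs(xy3[["x"]] - 0.30), 0.02)
  expect_lt(abs(xy3[["y"]] + 0.20), 0.02)

  expect_error(xy_centroid(matrix(1, 8, 8), 100, cfg),
               class = "mprheo_degenerate_data")
})

test_that("sharpness matches hand-evaluated values and rewards concentration", {
  expect_equal(sharpness(matrix(2, 4, 4)), 0.03125)  # 16*(4-2)/32^2
  img <- matrix(0, 5, 5); img[3, 3] <- 10
  expect_equal(sharpness(img), 1 - 1 / 10)
  # concentrating fixed total intensity into fewer pixels raises sharpness:
  # brute force over two-pixel redistributions of total 60
  conc <- vapply(seq(30, 55, by = 5), function(a) {
    m <- matrix(0, 4, 4); m[1, 1] <- a; m[2, 2] <- 60 - a
    sharpness(m)
  }, 0)
  expect_true(all(diff(conc) > 0))
  expect_error(sharpness(matrix(0, 4, 4)), class = "mprheo_degenerate_data")
})

test_that("sharpness preprocessing removes background and sign", {
  cfg <- small_config()
  st <- split_frame(render_frame(c(0, 0, 0), cfg), cfg)
  # constant image -> all zeros
  stc <- st; stc$sub_images[] <- 50L
  expect_true(all(preprocess_for_sharpness(stc)$sub_images == 0))
  # dark bead and bright bead of equal magnitude -> identical sharpness
  bright <- st
  dark <- st
  dark$sub_images <- 2L * cfg$background_level - st$sub_images
  s_b <- sharpness_profile(preprocess_for_sharpness(bright))$values
  s_d <- sharpness_profile(preprocess_for_sharpness(dark))$values
  expect_equal(s_b, s_d)
  # a bead-free noisy tile has far lower sharpness than a bead tile
  cfgp <- small_config(noise_model = "poisson")
  stp <- split_frame(render_frame(c(0, 0, 0), cfgp, seed = 2), cfgp)
  empty <- stp
  set.seed(3)
  empty$sub_images[] <- rpois(length(empty$sub_images), cfgp$background_level)
  s_bead <- sharpness_profile(preprocess_for_sharpness(stp))$values
  s_empty <- sharpness_profile(preprocess_for_sharpness(empty))$values
  expect_gt(max(s_bead), 5 * max(s_empty))
})

test_that("centre of sharpness is the sharpness-weighted plane depth", {
  cfg <- optical_config()
  dz <- cfg$plane_spacing
  expect_equal(center_of_sharpness(make_profile(c(1, 2, 4, 8, 9, 8, 4, 2, 1))), 0)
  expect_equal(center_of_sharpness(make_profile(c(0, 0, 0, 0, 0, 0, 1, 0, 0))),
               2 * dz)
  expect_equal(center_of_sharpness(make_profile(c(0, 0, 0, 0, 1, 1, 0, 0, 0))),
               dz / 2)
  expect_error(center_of_sharpness(make_profile(rep(0, 9))),
               class = "mprheo_degenerate_data")
})

test_that("sharpest-plane estimate sits dz/4 toward the runner-up", {
  dz <- 0.88
  p <- make_profile(c(1, 2, 3, 5, 9, 8, 3, 2, 1))   # sharpest 0, second +1
  expect_equal(sharpest_plane_z(p), 0.22)
  p2 <- make_profile(c(1, 2, 3, 8, 9, 5, 3, 2, 1))  # second is -1
  expect_equal(sharpest_plane_z(p2), -0.22)
  # exact tie broken toward the mid-plane, deterministically
  p3 <- make_profile(c(1, 2, 3, 9, 9, 5, 3, 2, 1))  # tie between -1 and 0
  expect_equal(sharpest_plane_z(p3), 0 - (0 - -dz) / 4)
})

test_that("z_SP of a noise-free scan is a staircase on the dz/2 lattice", {
  cfg <- small_config()
  dz <- cfg$plane_spacing
  zs <- seq(-1.5, 1.5, by = 0.05)
  tr <- track(render_zscan(zs, cfg, seed = 1), cfg, calibration = "none")
  zsp <- tr$track$z_sp_um
  # every value on the lattice {n dz +/- dz/4}
  expect_true(all(abs(zsp / (dz / 4) - round(zsp / (dz / 4))) < 1e-9))
  expect_true(all(round(zsp / (dz / 4)) %% 2 != 0))
  # consecutive distinct values differ by exactly dz/2
  expect_equal(diff(unique(zsp)), rep(dz / 2, length(unique(zsp)) - 1))
  # monotone staircase tracking the motion
  expect_true(all(diff(zsp) >= 0))
})

test_that("z_CS under-estimates axial motion before rescaling", {
  cfg <- small_config()
  zs <- seq(-1, 1, by = 0.05)
  tr <- track(render_zscan(zs, cfg, seed = 1), cfg, calibration = "none")
  g <- unname(coef(lm(tr$track$z_cs_um ~ zs))[2])
  expect_gt(g, 0)
  expect_lt(g, 1)
  # and z_CS is monotone in true z over the central region (noise off)
  expect_true(all(diff(tr$track$z_cs_um) > 0))
})

test_that("calibration fit recovers a constructed linear relation", {
  cfg <- optical_config()
  z_sp <- rep(seq(-2, 2, by = 0.44), each = 5)
  z_cs <- z_sp / 5
  model <- fit_calibration(z_cs, z_sp, cfg)
  expect_equal(model$gradient, 5, tolerance = 1e-6)
  expect_equal(apply_calibration(0.1 + model$center, model) - model$offset,
               0.5, tolerance = 1e-6)
  expect_error(fit_calibration(z_cs[1:10], z_sp[1:10], cfg),
               class = "mprheo_insufficient_data")
  expect_error(fit_calibration(rep(c(0.1, 0, -0.1), 10),
                               rep(c(-0.44, 0, 0.44), 10), cfg),
               class = "mprheo_calibration_error")  # negative gradient
})

test_that("applying the calibration is the stated affine map", {
  model <- structure(list(gradient = 5.26, offset = 0, center = 0,
                          fit_range = c(-1, 1), n_points = 50,
                          plane_spacing = 0.88),
                     class = "calibration_model")
  expect_equal(apply_calibration(0.1, model), 0.526)
  expect_equal(apply_calibration(model$center, model), model$offset)
  a <- 0.07; b <- -0.12
  expect_equal(apply_calibration(a, model) + apply_calibration(b, model) -
                 apply_calibration(0, model),
               apply_calibration(a + b, model))
})

test_that("tracking a static centred bead returns a constant origin", {
  cfg <- small_config()
  frames <- render_zscan(rep(0, 3)[1], cfg, seed = 1)  # single frame
  frames <- c(frames, frames, frames)
  tr <- track(frames, cfg, calibration = "none", frame_rate = 67)
  expect_true(all(abs(tr$track$x_um) < 1e-9))
  expect_true(all(abs(tr$track$y_um) < 1e-9))
  expect_true(all(abs(tr$track$z_cs_um) < 0.02))
  expect_true(all(tr$track$sharpest_plane == 0))
})

test_that("self-calibrated tracking recovers true z with unit gradient", {
  cfg <- small_config(noise_model = "poisson")
  zs <- seq(-1.8, 1.8, by = 0.05)
  tr <- track(render_zscan(zs, cfg, seed = 21), cfg, calibration = "self")
  sel <- abs(zs) <= 1
  g <- unname(coef(lm(tr$track$z_rcs_um[sel] ~ zs[sel]))[2])
  expect_equal(g, 1, tolerance = 0.02)
  # and a tracked trajectory correlates with truth on every axis
  p <- water_trap(kappa_z = 2e-8)  # weak axial trap: visible z motion
  traj <- simulate_trajectory(p, 67, 40, seed = 6)
  movie <- render_trajectory_frames(traj, cfg, seed = 7)
  model <- tr$calibration
  tm <- track(movie, cfg, calibration = model, frame_rate = 67)
  for (ax in c("x", "y")) {
    est <- tm$track[[paste0(ax, "_um")]]
    expect_gt(cor(est, traj$positions[, ax]), 0.99)
  }
  expect_gt(cor(tm$track$z_rcs_um, traj$positions[, "z"]), 0.95)
})

test_that("plane-spacing characterisation recovers the configured spacing", {
  base <- small_config()
  zs <- seq(-4, 4, by = 0.1)
  est <- characterize_plane_spacing(render_zscan(zs, base, seed = 2), zs, base)
  expect_equal(est$plane_spacing, base$plane_spacing, tolerance = 0.02)

  # doubling the configured spacing doubles the estimate
  wide <- small_config(plane_spacing = 1.76)
  zs2 <- seq(-8, 8, by = 0.2)
  est2 <- characterize_plane_spacing(render_zscan(zs2, wide, seed = 2), zs2, wide)
  expect_equal(est2$plane_spacing / est$plane_spacing, 2, tolerance = 0.04)

  # translation of the stage origin leaves the estimate unchanged
  frames <- render_zscan(zs, base, seed = 3)
  e_a <- characterize_plane_spacing(frames, zs, base)
  e_b <- characterize_plane_spacing(frames, zs + 5, base)
  expect_equal(e_a$plane_spacing, e_b$plane_spacing, tolerance = 1e-12)

  expect_error(
    suppressWarnings(
      characterize_plane_spacing(render_zscan(seq(-0.1, 0.1, by = 0.05), base,
                                              seed = 1),
                                 seq(-0.1, 0.1, by = 0.05), base)),
    class = "mprheo_insufficient_data")
})
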