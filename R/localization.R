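# Multiplane localisation: tiled frame -> (x, y, z).
#
# Pipeline per frame (matching the instrument's image-processing chain):
#   split_frame -> otsu_threshold -> xy_centroid (on the sharpest plane's
#   thresholded raw sub-image); in parallel preprocess_for_sharpness ->
#   sharpness per plane -> centre-of-sharpness z_CS and sharpest-plane z_SP.
# A linear fit of the stepped z_SP against z_CS, obtained from an in-situ
# calibration sweep, rescales the smooth-but-biased z_CS into the final
# axial coordinate z_RCS.

#' Split a tiled frame into its per-plane sub-images
#'
#' @param frame A `raw_frame` (or a bare integer matrix).
#' @param config An [optical_config()] describing the tile grid and layout.
#' @return A `plane_stack`: list with `sub_images` (tile_pixels x
#'   tile_pixels x n_planes array, ordered by ascending plane index),
#'   `plane_index` and `plane_z` [um].
#' @export
split_frame <- function(frame, config) {
  stopifnot(inherits(config, "optical_config"))
  img <- if (inherits(frame, "raw_frame")) frame$image else frame
  n <- config$tile_pixels
  rows <- config$tile_shape[1]; cols <- config$tile_shape[2]
  if (!identical(dim(img), as.integer(c(rows * n, cols * n))))
    mp_stop("mprheo_format_error",
            "frame is %d x %d but the %dx%d tile grid of %d px tiles requires %d x %d",
            nrow(img), ncol(img), rows, cols, n, rows * n, cols * n)
  idx <- plane_indices(config)
  subs <- array(0L, c(n, n, config$n_planes))
  for (k in seq_len(config$n_planes)) {
    r0 <- ((k - 1) %/% cols) * n
    c0 <- ((k - 1) %% cols) * n
    pos <- match(config$tile_layout[k], idx)
    subs[, , pos] <- img[r0 + seq_len(n), c0 + seq_len(n)]
  }
  structure(list(sub_images = subs, plane_index = idx,
                 plane_z = idx * config$plane_spacing),
            class = "plane_stack")
}

#' Reassemble a plane stack into a tiled frame
#'
#' Inverse of [split_frame()]; mainly used to verify that splitting is
#' lossless.
#' @param stack A `plane_stack`.
#' @param config The [optical_config()] used to split.
#' @return An integer matrix of the original tiled dimensions.
#' @export
assemble_frame <- function(stack, config) {
  n <- config$tile_pixels
  rows <- config$tile_shape[1]; cols <- config$tile_shape[2]
  img <- matrix(0L, rows * n, cols * n)
  for (k in seq_len(config$n_planes)) {
    r0 <- ((k - 1) %/% cols) * n
    c0 <- ((k - 1) %% cols) * n
    pos <- match(config$tile_layout[k], stack$plane_index)
    img[r0 + seq_len(n), c0 + seq_len(n)] <- stack$sub_images[, , pos]
  }
  img
}

#' Otsu threshold over a pooled plane stack
#'
#' Computes a single global intensity threshold for all planes of one frame
#' by Otsu's criterion (maximise inter-class variance) on the pooled integer
#' histogram. Pooling across planes keeps the bead above threshold even in
#' strongly defocused planes where a per-plane threshold could lose it.
#'
#' @param stack A `plane_stack` (or any integer array/matrix).
#' @return The threshold level; foreground is `intensity >= threshold`.
#' @export
otsu_threshold <- function(stack) {
  x <- if (inherits(stack, "plane_stack")) stack$sub_images else stack
  x <- as.integer(round(as.numeric(x)))
  mp_check(length(x) > 0, "mprheo_degenerate_data", "empty image stack")
  lo <- min(x); hi <- max(x)
  if (lo == hi)
    mp_stop("mprheo_degenerate_data",
            "constant image (all pixels %d): no threshold exists", lo)
  counts <- tabulate(x - lo + 1L, nbins = hi - lo + 1L)
  levels <- as.numeric(lo:hi)
  w <- cumsum(counts)                      # class-0 size for t = level k
  mu <- cumsum(counts * levels)
  n <- length(x); mu_t <- mu[length(mu)]
  w1 <- n - w
  valid <- w > 0 & w1 > 0
  between <- rep(-Inf, length(levels))
  between[valid] <- (mu_t * w[valid] - n * mu[valid])^2 /
    (w[valid] * w1[valid])
  k <- which.max(between)
  # foreground = pixels strictly above the Otsu level; return the midpoint
  # so callers can use >= uniformly
  levels[k] + 0.5
}

#' Centre-of-mass lateral localisation
#'
#' Thresholds a sub-image (pixels below the threshold are zeroed) and takes
#' the intensity-weighted centre of mass of the remainder, in micrometres.
#' Pixel centres sit at integer indices and the origin is the sub-image
#' centre, so a perfectly centred symmetric bead returns (0, 0). Rows are
#' the y coordinate, columns x.
#'
#' @param image A sub-image matrix (raw counts).
#' @param threshold Intensity threshold (see [otsu_threshold()]).
#' @param config An [optical_config()] (provides the pixel size).
#' @return Named numeric `c(x, y)` [um].
#' @export
xy_centroid <- function(image, threshold, config) {
  w <- ifelse(image >= threshold, as.numeric(image), 0)
  tot <- sum(w)
  if (tot <= 0)
    mp_stop("mprheo_degenerate_data",
            "no pixels at or above threshold %.6g: no object to localise",
            threshold)
  coords <- tile_coords(config)
  c(x = sum(colSums(w) * coords) / tot,
    y = sum(rowSums(w) * coords) / tot)
}

#' Image sharpness
#'
#' The normalised second-moment sharpness metric
#' `S = sum(I^2 - I) / sum(I)^2`, computed on a background-subtracted
#' absolute-intensity image (see [preprocess_for_sharpness()]). S peaks when
#' the bead is in focus and falls off as defocus spreads the same integrated
#' signal over more pixels.
#'
#' @param image Background-subtracted absolute-intensity matrix.
#' @return Dimensionless sharpness value.
#' @export
sharpness <- function(image) {
  s1 <- sum(image)
  if (s1 <= 0)
    mp_stop("mprheo_degenerate_data", "all-zero image: sharpness undefined")
  sum(image^2 - image) / s1^2
}

#' Prepare a plane stack for sharpness computation
#'
#' Per plane: subtract the sub-image median (a robust background estimate
#' while the bead occupies a minority of the tile) and take absolute pixel
#' values. The absolute value makes the metric indifferent to whether the
#' bead is brighter or darker than the background.
#'
#' @param stack A `plane_stack`.
#' @return A `plane_stack` with double-valued sub-images.
#' @export
preprocess_for_sharpness <- function(stack) {
  stopifnot(inherits(stack, "plane_stack"))
  out <- stack
  subs <- array(0, dim(stack$sub_images))
  for (k in seq_along(stack$plane_index)) {
    s <- as.numeric(stack$sub_images[, , k])
    subs[, , k] <- abs(s - median(s))
  }
  out$sub_images <- subs
  out
}

#' Per-plane sharpness profile of a frame
#'
#' @param stack A preprocessed `plane_stack` (see
#'   [preprocess_for_sharpness()]).
#' @return A `sharpness_profile`: list with `values` (one per plane),
#'   `plane_index` and `plane_z` [um].
#' @export
sharpness_profile <- function(stack) {
  stopifnot(inherits(stack, "plane_stack"))
  vals <- vapply(seq_along(stack$plane_index),
                 function(k) sharpness(stack$sub_images[, , k]), 0)
  structure(list(values = vals, plane_index = stack$plane_index,
                 plane_z = stack$plane_z),
            class = "sharpness_profile")
}

#' Centre of sharpness: smooth axial estimate
#'
#' Sharpness-weighted mean of the plane depths,
#' `z_CS = sum(z_plane * S_plane) / sum(S_plane)` -- the axial analogue of
#' an intensity centre of mass. With few planes it systematically
#' under-estimates displacement (its gradient against true z is well below
#' one), which is what the in-situ rescaling corrects.
#'
#' @param profile A `sharpness_profile`.
#' @return z_CS [um].
#' @export
center_of_sharpness <- function(profile) {
  stopifnot(inherits(profile, "sharpness_profile"))
  mp_check(length(profile$values) >= 2, "mprheo_invalid_parameter",
           "need at least 2 planes")
  tot <- sum(profile$values)
  if (tot <= 0)
    mp_stop("mprheo_degenerate_data",
            "zero total sharpness: centre of sharpness undefined")
  sum(profile$plane_z * profile$values) / tot
}

#' Sharpest-plane axial estimate
#'
#' Quantised axial estimate from the two sharpest planes:
#' `z_SP = z_sharpest - (z_sharpest - z_2nd_sharpest) / 4`. When the two
#' sharpest planes are adjacent this equals `z_sharpest +/- dz/4`, so a bead
#' moving through z produces a staircase with even steps of dz/2. Exact
#' sharpness ties are broken toward the plane nearer the mid-plane (they
#' have probability zero in the presence of noise).
#'
#' @param profile A `sharpness_profile`.
#' @return z_SP [um].
#' @export
sharpest_plane_z <- function(profile) {
  stopifnot(inherits(profile, "sharpness_profile"))
  mp_check(length(profile$values) >= 2, "mprheo_invalid_parameter",
           "need at least 2 planes")
  ord <- order(-profile$values, abs(profile$plane_index))
  z1 <- profile$plane_z[ord[1]]
  z2 <- profile$plane_z[ord[2]]
  z1 - (z1 - z2) / 4
}

#' Fit the in-situ axial rescaling calibration
#'
#' During a calibration sweep the bead is moved through z; the staircase
#' z_SP (accurate on average, quantised to dz/2) is regressed on the smooth
#' z_CS, and the slope becomes the rescale factor mapping z_CS onto real
#' micrometres. Guards against the known failure modes of the raw series:
#' frames whose sharpest plane is an edge plane (|n| >= 3) are dropped, the
#' fit is restricted to the central near-linear region (|z_SP| <= 2 dz by
#' default), and z_CS is median-centred so the trap/scan centre defines
#' z = 0.
#'
#' @param z_cs,z_sp Equal-length numeric series from the sweep [um].
#' @param config An [optical_config()] (provides the plane spacing).
#' @param sharpest_index Optional integer series of per-frame sharpest-plane
#'   indices, used to drop edge-plane frames.
#' @param max_abs_zsp Half-width of the fitted z_SP region [um]; default
#'   `2 * plane_spacing`.
#' @return A `calibration_model`: gradient (dimensionless), offset [um],
#'   center (the subtracted z_CS constant), fit_range, n_points,
#'   plane_spacing.
#' @export
fit_calibration <- function(z_cs, z_sp, config, sharpest_index = NULL,
                            max_abs_zsp = 2 * config$plane_spacing) {
  mp_check(length(z_cs) == length(z_sp), "mprheo_invalid_parameter",
           "z_cs and z_sp must have equal length")
  keep <- abs(z_sp) <= max_abs_zsp
  if (!is.null(sharpest_index)) keep <- keep & abs(sharpest_index) < 3
  n_steps <- length(unique(z_sp[keep]))
  if (sum(keep) < 20 || n_steps < 3)
    mp_stop("mprheo_insufficient_data",
            "calibration sweep needs >= 20 usable samples over >= 3 distinct z_SP steps (have %d over %d)",
            sum(keep), n_steps)
  center <- median(z_cs[keep])
  xc <- z_cs[keep] - center
  fit <- lm(z_sp[keep] ~ xc)
  gradient <- unname(coef(fit)[2])
  if (!is.finite(gradient) || gradient <= 0)
    mp_stop("mprheo_calibration_error",
            "calibration failed: non-positive gradient %.4g", gradient)
  structure(list(gradient = gradient, offset = unname(coef(fit)[1]),
                 center = center, fit_range = range(z_sp[keep]),
                 n_points = sum(keep), plane_spacing = config$plane_spacing),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "Axial rescaling calibration: gradient %.4g, offset %.4g um (n = %d, z_SP in [%.3g, %.3g] um)\n",
    x$gradient, x$offset, x$n_points, x$fit_range[1], x$fit_range[2]))
  invisible(x)
}

#' Apply the axial rescaling calibration
#'
#' `z_RCS = gradient * (z_CS - center) + offset`: the rescaled centre of
#' sharpness, the final axial coordinate.
#'
#' @param z_cs Centre-of-sharpness value(s) [um].
#' @param model A `calibration_model` from [fit_calibration()].
#' @return z_RCS [um].
#' @export
apply_calibration <- function(z_cs, model) {
  stopifnot(inherits(model, "calibration_model"))
  model$gradient * (z_cs - model$center) + model$offset
}

#' Track a bead through a sequence of tiled multiplane frames
#'
#' Runs the full localisation chain on every frame: split into planes,
#' pooled Otsu threshold, x-y centre of mass on the sharpest plane's
#' thresholded sub-image, background-subtract/absolute-value preprocessing,
#' per-plane sharpness, z_CS and z_SP; then fits (or applies) the axial
#' rescaling calibration to produce z_RCS.
#'
#' @param frames List of `raw_frame` objects (or integer matrices).
#' @param config An [optical_config()].
#' @param calibration `"self"` (fit the rescaling from this sequence, the
#'   in-situ procedure), a `calibration_model` to apply, or `"none"`
#'   (z_RCS left `NA`).
#' @param calibration_frames Indices of the frames forming the calibration
#'   sweep when `calibration = "self"`; default all frames (appropriate when
#'   the whole sequence is a sweep, e.g. a stage scan).
#' @param frame_rate Frame rate [Hz] recorded in the result (used when
#'   frames carry no timestamps).
#' @return A `tracking_result`: data frame `$track` with columns `frame`,
#'   `time_s`, `x_um`, `y_um`, `z_cs_um`, `z_sp_um`, `z_rcs_um`,
#'   `sharpest_plane`; plus `$calibration` and `$profiles` (frames x planes
#'   sharpness matrix).
#' @export
track <- function(frames, config, calibration = "self",
                  calibration_frames = NULL, frame_rate = NULL) {
  stopifnot(inherits(config, "optical_config"))
  mp_check(length(frames) >= 1, "mprheo_invalid_parameter", "no frames")
  nf <- length(frames)
  res <- data.frame(frame = seq_len(nf), time_s = NA_real_,
                    x_um = NA_real_, y_um = NA_real_, z_cs_um = NA_real_,
                    z_sp_um = NA_real_, z_rcs_um = NA_real_,
                    sharpest_plane = NA_integer_)
  profiles <- matrix(NA_real_, nf, config$n_planes)
  colnames(profiles) <- paste0("n", plane_indices(config))
  for (i in seq_len(nf)) {
    fr <- frames[[i]]
    stack <- tryCatch(split_frame(fr, config), mprheo_error = function(e)
      mp_stop(class(e)[1], "frame %d: %s", i, conditionMessage(e)))
    prep <- preprocess_for_sharpness(stack)
    prof <- sharpness_profile(prep)
    k_sharp <- which.max(prof$values)
    thr <- otsu_threshold(stack)
    xy <- xy_centroid(stack$sub_images[, , k_sharp], thr, config)
    res$time_s[i] <- if (inherits(fr, "raw_frame")) fr$timestamp else
      (i - 1) / (frame_rate %||% 1)
    res$x_um[i] <- xy[["x"]]
    res$y_um[i] <- xy[["y"]]
    res$z_cs_um[i] <- center_of_sharpness(prof)
    res$z_sp_um[i] <- sharpest_plane_z(prof)
    res$sharpest_plane[i] <- stack$plane_index[k_sharp]
    profiles[i, ] <- prof$values
  }
  model <- NULL
  if (inherits(calibration, "calibration_model")) {
    model <- calibration
  } else if (identical(calibration, "self")) {
    idx <- calibration_frames %||% seq_len(nf)
    model <- fit_calibration(res$z_cs_um[idx], res$z_sp_um[idx], config,
                             sharpest_index = res$sharpest_plane[idx])
  } else if (!identical(calibration, "none")) {
    mp_stop("mprheo_invalid_parameter",
            "calibration must be 'self', 'none', or a calibration_model")
  }
  if (!is.null(model)) res$z_rcs_um <- apply_calibration(res$z_cs_um, model)
  structure(list(track = res, calibration = model, profiles = profiles,
                 frame_rate = frame_rate),
            class = "tracking_result")
}

#' @export
print.tracking_result <- function(x, ...) {
  cat(sprintf("Tracking result: %d frames\n", nrow(x$track)))
  if (!is.null(x$calibration)) print(x$calibration)
  print(utils::head(x$track, 4))
  invisible(x)
}

#' Convert a tracking result into a trajectory
#'
#' Uses x, y and the rescaled axial coordinate z_RCS as the 3D positions.
#' @param result A `tracking_result` with calibration applied.
#' @param frame_rate Frame rate [Hz] if timestamps are missing/constant.
#' @return A `trajectory` object.
#' @export
as_trajectory <- function(result, frame_rate = NULL) {
  stopifnot(inherits(result, "tracking_result"))
  tr <- result$track
  mp_check(!anyNA(tr$z_rcs_um), "mprheo_invalid_parameter",
           "tracking result has no calibrated z_rcs values")
  times <- tr$time_s
  if (anyNA(times) || length(unique(round(diff(times), 12))) > 1) {
    fr <- frame_rate %||% result$frame_rate %||% 1
    times <- (seq_len(nrow(tr)) - 1) / fr
  }
  new_trajectory(times, cbind(x = tr$x_um, y = tr$y_um, z = tr$z_rcs_um))
}

#' Measure the inter-plane spacing from a fixed-bead z-scan
#'
#' The system-characterisation procedure: scan a fixed bead through z with
#' a calibrated stage, find for every plane the stage position that
#' maximises that plane's sharpness (three-point parabolic interpolation
#' around the discrete maximum, since stage steps under-sample the peak),
#' and fit peak position against plane index. The slope is the plane
#' spacing.
#'
#' @param zscan_frames List of `raw_frame`s from the scan.
#' @param stage_z Monotone stage positions [um], one per frame.
#' @param config An [optical_config()].
#' @param peak_halfwidth Half-width [um] of the stage window around each
#'   plane's discrete sharpness maximum used for the parabolic fit.
#'   Default 0.5 um: wide enough to average the shot noise of many scan
#'   steps, still well inside the quadratic cap of the sharpness peak.
#' @return List with `plane_spacing` [um], `peaks` (per-plane peak stage
#'   positions) and `plane_index`.
#' @export
characterize_plane_spacing <- function(zscan_frames, stage_z, config,
                                       peak_halfwidth = 0.5) {
  mp_check(length(zscan_frames) == length(stage_z),
           "mprheo_invalid_parameter",
           "need one stage position per frame")
  nf <- length(zscan_frames)
  S <- matrix(NA_real_, nf, config$n_planes)
  for (i in seq_len(nf)) {
    prof <- sharpness_profile(preprocess_for_sharpness(
      split_frame(zscan_frames[[i]], config)))
    S[i, ] <- prof$values
  }
  idx <- plane_indices(config)
  step <- mean(abs(diff(stage_z)))
  hw <- max(1L, as.integer(round(peak_halfwidth / step)))
  peaks <- rep(NA_real_, length(idx))
  for (k in seq_along(idx)) {
    j <- which.max(S[, k])
    if (j <= hw || j > nf - hw) {
      warning(sprintf(
        "plane n = %d: sharpness maximum at the scan edge; excluded", idx[k]),
        call. = FALSE)
      next
    }
    # parabola fitted over the +/- peak_halfwidth stage window
    w <- (j - hw):(j + hw)
    co <- coef(lm(S[w, k] ~ stats::poly(stage_z[w], 2, raw = TRUE)))
    peaks[k] <- if (is.finite(co[3]) && co[3] < 0) {
      unname(-co[2] / (2 * co[3]))
    } else stage_z[j]
  }
  usable <- is.finite(peaks)
  if (sum(usable) < 3)
    mp_stop("mprheo_insufficient_data",
            "only %d planes have an interior sharpness maximum; need >= 3",
            sum(usable))
  fit <- lm(peaks[usable] ~ idx[usable])
  list(plane_spacing = unname(coef(fit)[2]), peaks = peaks,
       plane_index = idx)
}
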