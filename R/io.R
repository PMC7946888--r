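# File formats: multi-page 16-bit TIFF for tiled frames (one page per time
# point, identical layout to the instrument camera), CSV for trajectories /
# stage logs / results (units encoded in column names), YAML for
# configuration. All round-trips are exact for the integer images and to
# full double precision read-back for CSVs.

#' Write / read tiled multiplane frames as multi-page TIFF
#'
#' One TIFF page per frame, 16-bit; pixel values and page order round-trip
#' exactly. Ground truth (when present in the frames) can be written to a
#' CSV sidecar with columns `frame`, `time_s`, `x_um`, `y_um`, `z_um`.
#'
#' @param frames List of `raw_frame` objects (or integer matrices).
#' @param path Output TIFF path.
#' @param truth_path Optional path for the ground-truth sidecar CSV.
#' @return `path`, invisibly.
#' @export
write_frames <- function(frames, path, truth_path = NULL) {
  mp_check(length(frames) >= 1, "mprheo_invalid_parameter", "no frames")
  imgs <- lapply(frames, function(f) {
    img <- if (inherits(f, "raw_frame")) f$image else f
    mp_check(all(img >= 0) && all(img <= 65535), "mprheo_format_error",
             "pixel values must be in [0, 65535] for 16-bit TIFF")
    img / 65535
  })
  tiff::writeTIFF(imgs, path, bits.per.sample = 16L)
  if (!is.null(truth_path)) {
    truth <- t(vapply(frames, function(f) {
      if (inherits(f, "raw_frame") && !is.null(f$truth))
        c(f$timestamp, f$truth) else rep(NA_real_, 4)
    }, numeric(4)))
    df <- data.frame(frame = seq_along(frames), time_s = truth[, 1],
                     x_um = truth[, 2], y_um = truth[, 3],
                     z_um = truth[, 4])
    write.csv(format(df, digits = 12, trim = TRUE), truth_path,
              row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_frames
#' @param timestamps Optional frame times [s] to attach on reading.
#' @return `read_frames`: a list of `raw_frame` objects.
#' @export
read_frames <- function(path, timestamps = NULL) {
  if (!file.exists(path))
    mp_stop("mprheo_format_error", "frame file not found: %s", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(seq_along(pages), function(i) {
    img <- pages[[i]]
    if (length(dim(img)) != 2)
      mp_stop("mprheo_format_error",
              "%s page %d: expected a single-channel 2D image", path, i)
    storage.mode(img) <- "integer"
    structure(list(image = img,
                   timestamp = if (!is.null(timestamps)) timestamps[i]
                               else i - 1,
                   truth = NULL),
              class = "raw_frame")
  })
}

#' Write / read a 3D trajectory as CSV
#'
#' Columns `time_s`, `x_um`, `y_um`, `z_um`; values written with 12
#' significant digits so read-back agrees to at least 9.
#'
#' @param traj A `trajectory`.
#' @param path CSV path.
#' @return `path` invisibly; `read_trajectory` returns a `trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  df <- data.frame(time_s = traj$times, x_um = traj$positions[, "x"],
                   y_um = traj$positions[, "y"], z_um = traj$positions[, "z"])
  write.csv(format(df, digits = 12, trim = TRUE), path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path))
    mp_stop("mprheo_format_error", "trajectory file not found: %s", path)
  df <- read.csv(path)
  need <- c("time_s", "x_um", "y_um", "z_um")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    mp_stop("mprheo_format_error", "%s: missing column(s) %s", path,
            paste(missing_cols, collapse = ", "))
  new_trajectory(df$time_s, cbind(x = df$x_um, y = df$y_um, z = df$z_um))
}

#' Read a stage-position log
#'
#' CSV with columns `frame` and `stage_z_um`, as produced by a calibrated
#' z-stage during a plane-spacing characterisation scan.
#' @param path CSV path.
#' @return Numeric vector of stage positions [um], ordered by frame.
#' @export
read_stage_log <- function(path) {
  if (!file.exists(path))
    mp_stop("mprheo_format_error", "stage log not found: %s", path)
  df <- read.csv(path)
  missing_cols <- setdiff(c("frame", "stage_z_um"), names(df))
  if (length(missing_cols))
    mp_stop("mprheo_format_error", "%s: missing column(s) %s", path,
            paste(missing_cols, collapse = ", "))
  df$stage_z_um[order(df$frame)]
}

#' Write / read run configuration as YAML
#'
#' Serialises an [optical_config()] and/or [trap_parameters()] (plus any
#' additional run options such as seeds and paths) into one flat,
#' human-editable YAML file. `read_config` validates and reconstructs the
#' typed objects, so a write/read cycle is idempotent.
#'
#' @param config A named list; entries `optical` (an `optical_config`) and
#'   `trap` (a `trap_parameters`) are serialised with their types, other
#'   entries verbatim.
#' @param path YAML path.
#' @return `path` invisibly; `read_config` returns the named list with
#'   `optical`/`trap` restored to their classes.
#' @export
write_config <- function(config, path) {
  ser <- config
  if (!is.null(ser$optical)) ser$optical <- unclass(ser$optical)
  if (!is.null(ser$trap)) ser$trap <- unclass(ser$trap)
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    mp_stop("mprheo_format_error", "config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  out <- raw
  if (!is.null(raw$optical))
    out$optical <- tryCatch(do.call(optical_config, raw$optical),
                            mprheo_error = function(e) mp_stop(
                              class(e)[1], "%s: invalid optical config: %s",
                              path, conditionMessage(e)))
  if (!is.null(raw$trap))
    out$trap <- tryCatch(do.call(trap_parameters, raw$trap),
                         mprheo_error = function(e) mp_stop(
                           class(e)[1], "%s: invalid trap parameters: %s",
                           path, conditionMessage(e)))
  out
}

#' Write a tracking result as CSV
#'
#' Columns `frame`, `time_s`, `x_um`, `y_um`, `z_cs_um`, `z_sp_um`,
#' `z_rcs_um`, `sharpest_plane`; the fitted calibration, if any, goes to a
#' YAML sidecar.
#'
#' @param result A `tracking_result`.
#' @param path CSV path.
#' @param calibration_path Optional YAML path for the calibration model.
#' @return `path`, invisibly.
#' @export
write_tracking_result <- function(result, path, calibration_path = NULL) {
  stopifnot(inherits(result, "tracking_result"))
  write.csv(format(result$track, digits = 12, trim = TRUE), path,
            row.names = FALSE, quote = FALSE)
  if (!is.null(calibration_path) && !is.null(result$calibration))
    yaml::write_yaml(unclass(result$calibration), calibration_path)
  invisible(path)
}
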