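#' Trap and fluid parameters for a trapped-bead simulation
#'
#' Bundles the physical parameters of an optically trapped bead in a
#' Newtonian fluid: per-axis trap stiffness, temperature, bead radius and
#' viscosities. The solvent viscosity `eta_s` is the (known) viscosity of the
#' pure solvent used to non-dimensionalise lag times; the fluid viscosity
#' `eta` is the viscosity actually experienced by the bead (equal to `eta_s`
#' for the pure solvent).
#'
#' @param kappa_x,kappa_y,kappa_z Trap stiffness per axis [N/m]. Typical
#'   optical traps fall in 1e-9 to 1e-5 N/m; values outside this range
#'   trigger a warning but are accepted.
#' @param temperature_K Absolute temperature [K]. Default 294 K (room
#'   temperature).
#' @param bead_radius Bead radius [m].
#' @param solvent_viscosity Solvent viscosity eta_s [Pa s].
#' @param fluid_viscosity Fluid viscosity eta [Pa s]; defaults to the
#'   solvent viscosity (pure Newtonian solvent).
#' @return An object of class `trap_parameters`.
#' @examples
#' p <- trap_parameters(kappa_x = 1e-7, kappa_y = 1e-7, kappa_z = 4e-8,
#'                      bead_radius = 3e-6, solvent_viscosity = 0.00095)
#' relaxation_time(p, "z")
#' @export
trap_parameters <- function(kappa_x, kappa_y, kappa_z,
                            temperature_K = 294,
                            bead_radius,
                            solvent_viscosity,
                            fluid_viscosity = solvent_viscosity) {
  vals <- c(kappa_x = kappa_x, kappa_y = kappa_y, kappa_z = kappa_z,
            temperature_K = temperature_K, bead_radius = bead_radius,
            solvent_viscosity = solvent_viscosity,
            fluid_viscosity = fluid_viscosity)
  mp_check(all(is.finite(vals)) && all(vals > 0), "mprheo_invalid_parameter",
           "all trap parameters must be finite and strictly positive")
  kap <- c(kappa_x, kappa_y, kappa_z)
  if (any(kap < 1e-9 | kap > 1e-5))
    warning("trap stiffness outside the usual optical-tweezers range ",
            "(1e-9 to 1e-5 N/m)", call. = FALSE)
  structure(as.list(vals), class = "trap_parameters")
}

#' @export
print.trap_parameters <- function(x, ...) {
  cat("Trap parameters:\n")
  cat(sprintf("  kappa (x, y, z): %.3g, %.3g, %.3g N/m\n",
              x$kappa_x, x$kappa_y, x$kappa_z))
  cat(sprintf("  T = %.1f K, r = %.3g m, eta_s = %.3g Pa s, eta = %.3g Pa s\n",
              x$temperature_K, x$bead_radius,
              x$solvent_viscosity, x$fluid_viscosity))
  invisible(x)
}

axis_kappa <- function(params, axis) {
  mp_check(axis %in% c("x", "y", "z"), "mprheo_invalid_parameter",
           "axis must be one of 'x', 'y', 'z'")
  params[[paste0("kappa_", axis)]]
}

#' Trap relaxation time
#'
#' The characteristic decay time of the position autocorrelation of an
#' overdamped bead in a harmonic trap, tau_c = 6 pi eta r / kappa. For a
#' Newtonian fluid the normalised position autocorrelation decays as
#' exp(-tau / tau_c).
#'
#' @param params A [trap_parameters()] object.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @return Relaxation time in seconds.
#' @export
relaxation_time <- function(params, axis) {
  stopifnot(inherits(params, "trap_parameters"))
  6 * pi * params$fluid_viscosity * params$bead_radius / axis_kappa(params, axis)
}

#' Analytic correlation functions of a trapped bead in a Newtonian fluid
#'
#' For an overdamped bead in a harmonic trap in a Newtonian fluid the
#' normalised position autocorrelation function is
#' `NPAF(tau) = exp(-kappa tau / (6 pi eta r))` and the normalised mean
#' squared displacement is `NMSD(tau) = 1 - NPAF(tau)`. These closed forms
#' serve as oracles for the empirical estimators in [compute_npaf()] and
#' [compute_nmsd()].
#'
#' @inheritParams relaxation_time
#' @param lag Lag time(s) in seconds, `>= 0`.
#' @return Dimensionless correlation value(s) in `[0, 1]`.
#' @export
analytic_npaf <- function(params, axis, lag) {
  mp_check(all(is.finite(lag)) && all(lag >= 0), "mprheo_domain_error",
           "lag times must be finite and non-negative")
  exp(-lag / relaxation_time(params, axis))
}

#' @rdname analytic_npaf
#' @export
analytic_nmsd <- function(params, axis, lag) {
  1 - analytic_npaf(params, axis, lag)
}

#' Simulate the trajectory of an optically trapped bead
#'
#' Each axis evolves as an independent stationary Ornstein-Uhlenbeck process
#' -- the overdamped Langevin dynamics of a bead in a harmonic trap -- using
#' the exact discrete-time transition
#' \deqn{x_{t+\Delta t} = x_t e^{-\Delta t/\tau_c} +
#'       \xi \sqrt{(k_B T/\kappa)(1 - e^{-2\Delta t/\tau_c})}}
#' with standard-normal noise, so the sampled process has the exact
#' stationary variance and autocorrelation at any frame rate (no
#' discretisation bias, unlike an Euler scheme). The initial position is
#' drawn from the equilibrium distribution (variance k_B T / kappa).
#'
#' @inheritParams relaxation_time
#' @param frame_rate Sampling rate [Hz].
#' @param n_frames Number of samples (`>= 2`).
#' @param seed Integer seed; identical seeds give bit-identical trajectories.
#' @return A `trajectory` object: list with `times` [s], `positions`
#'   (n x 3 matrix, columns `x`, `y`, `z`, displacements from the trap
#'   centre in micrometres), `frame_rate` and `seed`.
#' @export
simulate_trajectory <- function(params, frame_rate, n_frames, seed) {
  stopifnot(inherits(params, "trap_parameters"))
  mp_check(is.numeric(frame_rate) && frame_rate > 0, "mprheo_invalid_parameter",
           "frame_rate must be positive")
  mp_check(n_frames >= 2, "mprheo_invalid_parameter", "n_frames must be >= 2")
  n <- as.integer(n_frames)
  dt <- 1 / frame_rate
  set.seed(as.integer(seed))
  pos <- matrix(0, n, 3, dimnames = list(NULL, c("x", "y", "z")))
  for (ax in c("x", "y", "z")) {
    kappa <- axis_kappa(params, ax)
    tau_c <- relaxation_time(params, ax)
    sd_eq_um <- sqrt(kB * params$temperature_K / kappa) * 1e6
    a <- exp(-dt / tau_c)
    x0 <- rnorm(1) * sd_eq_um
    innov <- rnorm(n - 1) * (sd_eq_um * sqrt(1 - a^2))
    x <- stats::filter(innov, a, method = "recursive", init = x0)
    pos[, ax] <- c(x0, as.numeric(x))
  }
  new_trajectory(times = (seq_len(n) - 1) * dt, positions = pos,
                 frame_rate = frame_rate, seed = as.integer(seed))
}

#' Construct a trajectory object
#'
#' @param times Sample times [s], strictly increasing and uniformly spaced.
#' @param positions n x 3 numeric matrix of displacements [um], columns
#'   `x`, `y`, `z`.
#' @param frame_rate Sampling rate [Hz]; inferred from `times` if missing.
#' @param seed Optional integer seed recorded for provenance.
#' @return A `trajectory` object.
#' @export
new_trajectory <- function(times, positions, frame_rate = NULL, seed = NULL) {
  positions <- as.matrix(positions)
  mp_check(nrow(positions) >= 2 && ncol(positions) == 3,
           "mprheo_invalid_parameter",
           "positions must be an n x 3 matrix with n >= 2")
  mp_check(length(times) == nrow(positions), "mprheo_invalid_parameter",
           "times and positions must have equal length")
  mp_check(all(is.finite(positions)) && all(is.finite(times)),
           "mprheo_invalid_parameter", "times and positions must be finite")
  dts <- diff(times)
  mp_check(all(dts > 0), "mprheo_invalid_parameter",
           "times must be strictly increasing")
  mp_check(max(dts) - min(dts) <= 1e-9 * max(dts), "mprheo_invalid_parameter",
           "times must be uniformly spaced (relative tolerance 1e-9)")
  colnames(positions) <- c("x", "y", "z")
  structure(list(times = as.numeric(times), positions = positions,
                 frame_rate = frame_rate %||% (1 / mean(dts)),
                 seed = seed),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Bead trajectory: %d frames at %.4g Hz (%.4g s)\n",
              nrow(x$positions), x$frame_rate,
              x$times[length(x$times)] - x$times[1]))
  s <- apply(x$positions, 2, sd)
  cat(sprintf("  position sd [um]: x %.4g, y %.4g, z %.4g\n",
              s[1], s[2], s[3]))
  invisible(x)
}

traj_axis <- function(traj, axis) {
  stopifnot(inherits(traj, "trajectory"))
  mp_check(axis %in% c("x", "y", "z"), "mprheo_invalid_parameter",
           "axis must be one of 'x', 'y', 'z'")
  traj$positions[, axis]
}
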