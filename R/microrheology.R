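# Passive microrheology with optical tweezers: trajectory -> trap and
# fluid properties. For an overdamped bead in a harmonic trap in a
# Newtonian fluid, NPAF(tau) = exp(-kappa tau / (6 pi eta r)) and
# NMSD = 1 - NPAF, so on the dimensionless lag axis tau* =
# tau kappa / (6 pi r eta_s) the NPAF of the pure solvent crosses e^-1 at
# tau* = 1, and more generally at tau* = eta/eta_s: the relative viscosity
# can be read directly off the curve.

#' Equipartition trap stiffness
#'
#' `kappa = k_B T / <x^2>`, with the variance taken about the sample mean
#' and converted from um^2 to m^2.
#'
#' @param traj A `trajectory` (positions in um).
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param temperature_K Absolute temperature [K]. Default 294.
#' @return Trap stiffness [N/m].
#' @export
trap_stiffness <- function(traj, axis, temperature_K = 294) {
  x <- traj_axis(traj, axis)
  if (length(x) < 1000)
    warning("fewer than 1000 samples: equipartition stiffness will be noisy",
            call. = FALSE)
  v <- var(x) * 1e-12                     # um^2 -> m^2
  if (v <= 0)
    mp_stop("mprheo_degenerate_data",
            "zero position variance on axis %s", axis)
  kB * temperature_K / v
}

# Log-thinned lag indices from 1..max_k (plus lag 0), unique and sorted.
thin_lags <- function(max_k, n_lags) {
  ks <- unique(round(exp(seq(0, log(max_k), length.out = n_lags))))
  as.integer(ks[ks >= 1 & ks <= max_k])
}

new_correlation_curve <- function(df, axis, lag_unit) {
  structure(list(curve = df, axis = axis, lag_unit = lag_unit),
            class = "correlation_curve")
}

#' @export
print.correlation_curve <- function(x, ...) {
  cat(sprintf("Correlation curve (%s axis, lag in %s): %d lags\n",
              x$axis, x$lag_unit, nrow(x$curve)))
  print(utils::head(x$curve, 4))
  invisible(x)
}

#' Normalised position autocorrelation function (NPAF)
#'
#' `NPAF(tau) = <x(t) x(t+tau)> / <x^2>` over all available (overlapping)
#' pairs of the mean-subtracted series, evaluated at logarithmically
#' thinned lags; `NPAF(0) = 1` exactly.
#'
#' @param traj A `trajectory`.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param max_lag Largest lag [s]; default a tenth of the record duration
#'   (longer lags have too few effectively independent pairs).
#' @param n_lags Number of log-spaced lags. Default 80.
#' @return A `correlation_curve` with columns `lag` [s], `npaf`, `n_pairs`.
#' @export
compute_npaf <- function(traj, axis, max_lag = NULL, n_lags = 80) {
  x <- traj_axis(traj, axis)
  n <- length(x)
  dt <- 1 / traj$frame_rate
  duration <- (n - 1) * dt
  max_lag <- max_lag %||% (duration / 10)
  mp_check(max_lag >= dt, "mprheo_invalid_parameter",
           "max_lag shorter than one frame interval")
  x <- x - mean(x)
  v0 <- mean(x^2)
  if (v0 <= 0)
    mp_stop("mprheo_degenerate_data", "zero variance on axis %s", axis)
  ks <- thin_lags(floor(max_lag / dt), n_lags)
  ac <- vapply(ks, function(k)
    mean(x[seq_len(n - k)] * x[seq_len(n - k) + k]) / v0, 0)
  df <- data.frame(lag = c(0, ks * dt), npaf = c(1, ac),
                   n_pairs = c(n, n - ks))
  new_correlation_curve(df, axis, "s")
}

#' Normalised mean squared displacement (NMSD)
#'
#' `NMSD(tau) = <(x(t+tau) - x(t))^2> / (2 <x^2>)`, the squared-increment
#' estimator (independent of the autocorrelation estimator); for a
#' stationary series NMSD = 1 - NPAF.
#'
#' @inheritParams compute_npaf
#' @return A `correlation_curve` with columns `lag` [s], `nmsd`, `n_pairs`.
#' @export
compute_nmsd <- function(traj, axis, max_lag = NULL, n_lags = 80) {
  x <- traj_axis(traj, axis)
  n <- length(x)
  dt <- 1 / traj$frame_rate
  duration <- (n - 1) * dt
  max_lag <- max_lag %||% (duration / 10)
  mp_check(max_lag >= dt, "mprheo_invalid_parameter",
           "max_lag shorter than one frame interval")
  x <- x - mean(x)
  v0 <- mean(x^2)
  if (v0 <= 0)
    mp_stop("mprheo_degenerate_data", "zero variance on axis %s", axis)
  ks <- thin_lags(floor(max_lag / dt), n_lags)
  ms <- vapply(ks, function(k)
    mean((x[seq_len(n - k) + k] - x[seq_len(n - k)])^2) / (2 * v0), 0)
  df <- data.frame(lag = c(0, ks * dt), nmsd = c(0, ms),
                   n_pairs = c(n, n - ks))
  new_correlation_curve(df, axis, "s")
}

#' Rescale a correlation curve to the dimensionless lag-time
#'
#' Multiplies the lag axis by `kappa / (6 pi r eta_s)`, producing
#' `tau* = tau kappa / (6 pi r eta_s)`. On this axis the correlation curves
#' of all axes of one bead in one isotropic fluid collapse onto a single
#' master curve, and the NPAF crosses e^-1 at tau* equal to the relative
#' viscosity.
#'
#' @param curve A `correlation_curve` with lags in seconds.
#' @param kappa Trap stiffness of the curve's axis [N/m] (typically the
#'   equipartition estimate).
#' @param bead_radius Bead radius [m].
#' @param solvent_viscosity Solvent viscosity eta_s [Pa s].
#' @return The curve with `lag` replaced by tau* (`lag_unit = "tau_star"`).
#' @export
rescale_lags <- function(curve, kappa, bead_radius, solvent_viscosity) {
  stopifnot(inherits(curve, "correlation_curve"))
  mp_check(all(c(kappa, bead_radius, solvent_viscosity) > 0),
           "mprheo_invalid_parameter",
           "kappa, bead_radius and solvent_viscosity must be positive")
  out <- curve
  out$curve$lag <- curve$curve$lag * kappa /
    (6 * pi * bead_radius * solvent_viscosity)
  out$lag_unit <- "tau_star"
  out
}

#' Relative viscosity from the e^-1 crossing of the NPAF
#'
#' On the dimensionless lag axis, the first downward crossing of
#' `NPAF = e^-1` occurs at `tau* = eta / eta_s`: the relative viscosity,
#' read directly off the curve. The crossing is located by linear
#' interpolation of NPAF against log(tau*) between the bracketing samples
#' (the NPAF is exponential-like, hence near-linear in log-lag there).
#'
#' @param curve A `correlation_curve` in tau* (see [rescale_lags()]) with
#'   an `npaf` column.
#' @return Relative viscosity eta_r (dimensionless).
#' @export
relative_viscosity <- function(curve) {
  stopifnot(inherits(curve, "correlation_curve"))
  mp_check(identical(curve$lag_unit, "tau_star"), "mprheo_invalid_parameter",
           "curve must be rescaled to tau* first (see rescale_lags)")
  df <- curve$curve[curve$curve$lag > 0, ]
  e1 <- exp(-1)
  below <- which(df$npaf <= e1)
  if (length(below) == 0 || below[1] == 1)
    mp_stop("mprheo_insufficient_data",
            "NPAF does not cross e^-1 downward within the lag range; the record must span roughly >= 10 relaxation times (tau* up to ~%0.2g reached)",
            max(df$lag))
  j <- below[1]
  lt <- log(df$lag[(j - 1):j])
  pv <- df$npaf[(j - 1):j]
  exp(lt[1] + (e1 - pv[1]) * diff(lt) / diff(pv))
}

#' Trap-volume width (FWHM) of the position distribution
#'
#' Full width at half maximum of the equilibrium position distribution,
#' `2 sqrt(2 ln 2) * sd = 2.3548 sd`, using the Gaussian form of the
#' harmonic-trap equilibrium distribution.
#'
#' @inheritParams trap_stiffness
#' @return FWHM [um].
#' @export
fwhm <- function(traj, axis) {
  x <- traj_axis(traj, axis)
  if (length(x) < 1000)
    warning("fewer than 1000 samples: FWHM estimate will be noisy",
            call. = FALSE)
  s <- sd(x)
  if (s <= 0)
    mp_stop("mprheo_degenerate_data", "zero position variance on axis %s",
            axis)
  2 * sqrt(2 * log(2)) * s
}

#' Overlapping Allan deviation of the bead position
#'
#' Drift diagnostic: `sigma_A(tau) = sqrt(0.5 <(m_{i+1} - m_i)^2>)` over
#' consecutive (overlapping) cluster means of duration tau. For a
#' drift-free trapped bead the curve decays with cluster time; instrumental
#' drift makes it turn upward.
#'
#' @param traj A `trajectory`.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param cluster_sizes Integer cluster sizes [frames]; default octave
#'   spacing 1, 2, 4, ... up to a quarter of the record.
#' @return Data frame with `m` (cluster size), `tau` [s], `adev` [um].
#' @export
allan_deviation <- function(traj, axis, cluster_sizes = NULL) {
  x <- traj_axis(traj, axis)
  n <- length(x)
  dt <- 1 / traj$frame_rate
  cluster_sizes <- cluster_sizes %||% 2^(0:floor(log2(n / 4)))
  cluster_sizes <- as.integer(cluster_sizes)
  mp_check(all(cluster_sizes >= 1) && max(cluster_sizes) <= n / 4,
           "mprheo_invalid_parameter",
           "cluster sizes must be in [1, n/4] frames")
  cs <- cumsum(c(0, x))
  adev <- vapply(cluster_sizes, function(m) {
    means <- (cs[(m + 1):(n + 1)] - cs[1:(n - m + 1)]) / m
    d <- means[(m + 1):length(means)] - means[1:(length(means) - m)]
    if (length(d) < 2)
      mp_stop("mprheo_insufficient_data",
              "cluster size %d leaves too few clusters", m)
    sqrt(0.5 * mean(d^2))
  }, 0)
  data.frame(m = cluster_sizes, tau = cluster_sizes * dt, adev = adev)
}

#' Full per-axis microrheology analysis of a trajectory
#'
#' For each axis: equipartition trap stiffness, position variance and
#' trap-volume FWHM, and the relative viscosity from the e^-1 crossing of
#' the NPAF on the dimensionless lag axis (using the axis's own estimated
#' stiffness).
#'
#' @param traj A `trajectory`.
#' @param bead_radius Bead radius [m].
#' @param solvent_viscosity Solvent viscosity eta_s [Pa s].
#' @param temperature_K Absolute temperature [K]. Default 294.
#' @param max_lag,n_lags Passed to [compute_npaf()].
#' @return A `rheology_result`: list with `$table` (one row per axis:
#'   `axis`, `kappa_N_per_m`, `variance_um2`, `fwhm_um`, `eta_r`), the
#'   tau*-rescaled `$curves` per axis, and the input parameters.
#' @export
rheology <- function(traj, bead_radius, solvent_viscosity,
                     temperature_K = 294, max_lag = NULL, n_lags = 80) {
  axes <- c("x", "y", "z")
  rows <- list(); curves <- list()
  for (ax in axes) {
    kap <- trap_stiffness(traj, ax, temperature_K)
    curve <- rescale_lags(compute_npaf(traj, ax, max_lag, n_lags),
                          kap, bead_radius, solvent_viscosity)
    curves[[ax]] <- curve
    rows[[ax]] <- data.frame(
      axis = ax, kappa_N_per_m = kap,
      variance_um2 = var(traj_axis(traj, ax)),
      fwhm_um = fwhm(traj, ax),
      eta_r = relative_viscosity(curve))
  }
  structure(list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
                 curves = curves, bead_radius = bead_radius,
                 solvent_viscosity = solvent_viscosity,
                 temperature_K = temperature_K),
            class = "rheology_result")
}

#' @export
print.rheology_result <- function(x, ...) {
  cat(sprintf(
    "Microrheology result (r = %.3g m, eta_s = %.3g Pa s, T = %.1f K):\n",
    x$bead_radius, x$solvent_viscosity, x$temperature_K))
  print(x$table, row.names = FALSE)
  invisible(x)
}
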