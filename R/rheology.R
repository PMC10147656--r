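# Conversion of motion statistics to material properties via the
# generalized Stokes-Einstein relation, plus trap calibration, NPAF
# viscometry, angle-resolved viscosity and near-wall drag predictions.

#' Convert an MSD curve to creep compliance
#'
#' The probe MSD and the material's creep compliance are proportional:
#' \eqn{MSD(\tau) = (k_B T / \pi a) J(\tau)} (the literal published
#' convention, whose prefactor corresponds to a 3D MSD), or the
#' dimension-corrected form \eqn{J = 3\pi a/(d k_B T) \cdot MSD_d} that
#' makes a d-axis MSD physically consistent with equipartition; for
#' `d = 3` the two coincide. The convention used is recorded in the
#' output.
#'
#' @param msd An `msd_curve` carrying its probe context.
#' @param convention `"paper"` (literal, default for reproduction) or
#'   `"dimension_corrected"`.
#' @param terminal `"plateau"` (gels: the compliance saturates, terminal
#'   slope 0) or `"fluid"` (terminal slope `1/eta` estimated by a linear
#'   fit over the last decade of `J(t)`); alternatively supply
#'   `terminal_slope` directly (1/(Pa s)).
#' @param terminal_slope Optional numeric override of the extrapolation
#'   gradient beyond the last sample.
#' @return A `compliance_curve` with `t` (s), `J` (1/Pa),
#'   `terminal_slope`, `dimension`, `convention` and the context.
#' @export
msd_to_compliance <- function(msd, convention = c("paper",
                                                  "dimension_corrected"),
                              terminal = c("plateau", "fluid"),
                              terminal_slope = NULL) {
  stopifnot(inherits(msd, "msd_curve"))
  convention <- match.arg(convention)
  ctx <- msd$context
  if (is.null(ctx)) stop("MSD curve carries no probe context")
  kBT <- ctx$boltzmann_kB * ctx$temperature_T
  factor <- if (convention == "paper") pi * ctx$radius_a / kBT
            else 3 * pi * ctx$radius_a / (msd$dimension * kBT)
  J <- factor * msd$values
  if (is.null(terminal_slope)) {
    terminal <- match.arg(terminal)
    terminal_slope <- if (terminal == "plateau") 0 else {
      tail_idx <- which(msd$tau >= max(msd$tau) / 10)
      if (length(tail_idx) < 2L) tail_idx <- seq_along(msd$tau)
      stats::lm.fit(cbind(1, msd$tau[tail_idx]),
                    J[tail_idx])$coefficients[2L]
    }
  }
  structure(list(t = msd$tau, J = J, terminal_slope = terminal_slope,
                 dimension = msd$dimension, convention = convention,
                 context = ctx),
            class = "compliance_curve")
}

#' @export
print.compliance_curve <- function(x, ...) {
  cat(sprintf(
    "Compliance curve: %d points, J in [%.3g, %.3g] 1/Pa, %s convention, terminal slope %.3g\n",
    length(x$t), min(x$J), max(x$J), x$convention, x$terminal_slope))
  invisible(x)
}

#' Complex shear modulus from creep compliance
#'
#' Evaluates \eqn{G^\ast(\omega) = 1/(i\omega \hat J(\omega))} where
#' \eqn{\hat J} is the analytic Fourier transform of the piecewise-linear
#' interpolant of the sampled compliance, extended linearly from
#' \eqn{(0, J_0)} below the first sample and at `terminal_slope` beyond
#' the last. With
#' \deqn{D(\omega) = i\omega J_0
#'  + (1 - e^{-i\omega t_1})\frac{J_1 - J_0}{t_1}
#'  + \dot J_\infty e^{-i\omega t_N}
#'  + \sum_{k=2}^{N} \frac{J_k - J_{k-1}}{t_k - t_{k-1}}
#'    (e^{-i\omega t_{k-1}} - e^{-i\omega t_k})}
#' one has \eqn{(i\omega)^2 \hat J(\omega) = D(\omega)} (the sum is the
#' transform of the interpolant's second derivative), hence
#' \eqn{G^\ast(\omega) = i\omega / D(\omega)}. This data-driven transform
#' needs no functional form and is accurate across the sampled band.
#' \eqn{G'} and \eqn{G''} are the real and imaginary parts.
#'
#' @param J A `compliance_curve` with at least 10 samples.
#' @param omega Angular frequency grid (rad/s); default log-spaced, 10
#'   points/decade over \eqn{[2\pi/t_{max}, \pi/t_{min}]}. Frequencies
#'   outside the supported band \eqn{[1/t_{max}, \pi/t_{min}]} are
#'   trimmed with a warning.
#' @param J0 Compliance intercept at `t = 0` (default 0: the probe has
#'   not moved yet).
#' @param n_per_decade Grid density when `omega` is not supplied.
#' @return A `modulus_curve` with `omega`, `G_prime` and `G_doubleprime`
#'   (Pa).
#' @export
compliance_to_modulus <- function(J, omega = NULL, J0 = 0,
                                  n_per_decade = 10L) {
  stopifnot(inherits(J, "compliance_curve"))
  t <- J$t; Jv <- J$J
  if (length(t) < 10L) stop("need at least 10 compliance samples")
  lo <- 1 / max(t); hi <- pi / min(t)
  if (is.null(omega)) {
    omega <- 10^seq(log10(2 * pi / max(t)), log10(hi),
                    by = 1 / n_per_decade)
  } else {
    keep <- omega >= lo & omega <= hi
    if (!all(keep)) {
      warning(sprintf("%d frequencies outside the supported band [%.3g, %.3g] rad/s trimmed",
                      sum(!keep), lo, hi))
      omega <- omega[keep]
    }
    if (!length(omega)) stop("no frequencies left inside the supported band")
  }
  N <- length(t)
  E <- exp(-1i * outer(omega, t))             # n_omega x N
  slopes <- diff(Jv) / diff(t)                # k = 2..N term gradients
  D <- 1i * omega * J0 +
    (1 - E[, 1L]) * (Jv[1L] - J0) / t[1L] +
    J$terminal_slope * E[, N] +
    (E[, seq_len(N - 1L), drop = FALSE] -
       E[, 2L:N, drop = FALSE]) %*% slopes
  Gstar <- (1i * omega) / as.vector(D)
  structure(list(omega = omega, G_prime = Re(Gstar),
                 G_doubleprime = Im(Gstar), convention = J$convention),
            class = "modulus_curve")
}

#' @export
print.modulus_curve <- function(x, ...) {
  cat(sprintf("Complex modulus: %d frequencies in [%.3g, %.3g] rad/s\n",
              length(x$omega), min(x$omega), max(x$omega)))
  cat(sprintf("  G' range [%.3g, %.3g] Pa; G'' range [%.3g, %.3g] Pa\n",
              min(x$G_prime), max(x$G_prime), min(x$G_doubleprime),
              max(x$G_doubleprime)))
  invisible(x)
}

#' @export
plot.modulus_curve <- function(x, ...) {
  ok <- x$G_prime > 0 & x$G_doubleprime > 0
  graphics::matplot(x$omega[ok], cbind(x$G_prime[ok], x$G_doubleprime[ok]),
                    log = "xy", type = "l", lty = 1, col = c(2, 4),
                    xlab = expression(omega ~ (rad/s)),
                    ylab = "modulus (Pa)", ...)
  graphics::legend("topleft", legend = c("G'", "G''"), col = c(2, 4),
                   lty = 1, bty = "n")
  invisible(x)
}

#' Low-frequency plateau modulus from confined-position variance
#'
#' For a gel-trapped probe the elastic plateau follows directly from the
#' time-independent displacement variance:
#' \eqn{G_0' = k_B T / (\pi a \langle r^2\rangle)} (literal published
#' convention), or the dimension-corrected
#' \eqn{G_0' = d\, k_B T / (6 \pi a \langle r^2\rangle)} which inverts
#' the per-axis equipartition variance \eqn{k_B T/(6\pi a G_0)} of a
#' d-axis measurement and matches the dimension-corrected compliance
#' convention.
#'
#' @param variance Displacement variance \eqn{\langle r^2\rangle} in m^2,
#'   e.g. from [plateau_variance()] (its `dimension` attribute is used
#'   when present).
#' @param ctx A [probe_context()].
#' @param convention `"paper"` or `"dimension_corrected"`.
#' @param dimension Number of axes summed into `variance` (default from
#'   the attribute, else 3).
#' @return A `plateau_modulus` object with `G0_prime` (Pa),
#'   `variance_used`, `dimension` and `convention`.
#' @export
plateau_modulus <- function(variance, ctx,
                            convention = c("paper", "dimension_corrected"),
                            dimension = NULL) {
  convention <- match.arg(convention)
  stopifnot(inherits(ctx, "probe_context"))
  if (is.null(dimension))
    dimension <- if (!is.null(attr(variance, "dimension")))
      attr(variance, "dimension") else 3L
  v <- as.numeric(variance)
  if (!is.finite(v) || v <= 0) stop("variance must be strictly positive")
  kBT <- ctx$boltzmann_kB * ctx$temperature_T
  G0 <- if (convention == "paper") kBT / (pi * ctx$radius_a * v)
        else dimension * kBT / (6 * pi * ctx$radius_a * v)
  structure(list(G0_prime = G0, variance_used = v, dimension = dimension,
                 convention = convention),
            class = "plateau_modulus")
}

#' @export
print.plateau_modulus <- function(x, ...) {
  cat(sprintf("G0' = %.4g Pa (from <r^2> = %.3g m^2, d = %d, %s convention)\n",
              x$G0_prime, x$variance_used, x$dimension, x$convention))
  invisible(x)
}

#' Proportional change in the plateau modulus between two timepoints
#'
#' `(G0_t - G0_ref) / G0_ref`; negative values indicate the material has
#' become more compliant.
#'
#' @param G0_t,G0_ref Plateau moduli (Pa or `plateau_modulus` objects),
#'   both positive.
#' @export
delta_plateau <- function(G0_t, G0_ref) {
  g1 <- if (inherits(G0_t, "plateau_modulus")) G0_t$G0_prime else G0_t
  g0 <- if (inherits(G0_ref, "plateau_modulus")) G0_ref$G0_prime else G0_ref
  stopifnot(g1 > 0, g0 > 0)
  (g1 - g0) / g0
}

#' Trap stiffness by equipartition
#'
#' \eqn{\kappa = k_B T / \langle x^2 \rangle} from the stationary
#' position variance of one (detrended) axis.
#'
#' @param traj A [trajectory()].
#' @param axis Axis name.
#' @return Stiffness in N/m.
#' @export
trap_stiffness_equipartition <- function(traj, axis = "x") {
  stopifnot(inherits(traj, "trajectory"))
  x <- axis_series(traj, axis)
  v <- mean((x - mean(x))^2)
  if (v <= 0) stop("zero variance: cannot calibrate trap stiffness")
  traj$context$boltzmann_kB * traj$context$temperature_T / v
}

#' Relative viscosity from the NPAF e^-1 intercept
#'
#' When the NPAF of a trapped bead is plotted against the dimensionless
#' lag \eqn{\tau^\ast = \kappa\tau/(6\pi a \eta_s)}, a Newtonian medium
#' of viscosity \eqn{\eta} decays as \eqn{e^{-\tau^\ast \eta_s/\eta}}, so
#' the abscissa of the \eqn{e^{-1}} intercept reads out the relative
#' viscosity \eqn{\eta/\eta_s} at a glance. The crossing is located on
#' the first downward crossing with log-linear interpolation between the
#' bracketing samples (exact for exponential decay; robust to noisy
#' re-crossings at long lag).
#'
#' @param npaf An `npaf_curve`.
#' @param kappa Trap stiffness along the analysed axis (N/m), e.g. from
#'   [trap_stiffness_equipartition()].
#' @param ctx A [probe_context()] providing `a` and `eta_s`.
#' @return List of class `npaf_viscosity` with `eta_relative`, `kappa`
#'   and the NPAF curve with its `tau_star` axis filled in.
#' @export
relative_viscosity_npaf <- function(npaf, kappa, ctx) {
  stopifnot(inherits(npaf, "npaf_curve"), inherits(ctx, "probe_context"),
            kappa > 0)
  ts <- kappa * npaf$tau / (6 * pi * ctx$radius_a *
                              ctx$solvent_viscosity_eta_s)
  v <- npaf$values
  target <- exp(-1)
  i <- which(v[-length(v)] > target & v[-1L] <= target)
  if (!length(i))
    stop("NPAF does not cross e^-1 within the observed lags; ",
         "record a longer trajectory")
  i <- i[1L]
  cross <- if (v[i + 1L] > 0) {
    ts[i] + (log(v[i]) + 1) / (log(v[i]) - log(v[i + 1L])) *
      (ts[i + 1L] - ts[i])
  } else {
    ts[i] + (v[i] - target) / (v[i] - v[i + 1L]) * (ts[i + 1L] - ts[i])
  }
  npaf$tau_star <- ts
  structure(list(eta_relative = cross, kappa = kappa, npaf = npaf),
            class = "npaf_viscosity")
}

#' @export
print.npaf_viscosity <- function(x, ...) {
  cat(sprintf("NPAF relative viscosity: eta_r = %.4g (kappa = %.3g N/m)\n",
              x$eta_relative, x$kappa))
  invisible(x)
}

#' Angle-resolved viscosity from early-lag directional MSD
#'
#' In a purely viscous medium a trapped bead diffuses freely at lags much
#' shorter than the trap relaxation time, so Fick's law
#' \eqn{MSD(\tau,\theta,\varphi) = 2 D_{(\theta,\varphi)} \tau} holds in
#' any direction; the Stokes--Einstein relation
#' \eqn{D = k_B T/(6\pi\eta_{(\theta,\varphi)} a)} then converts the
#' early-lag slope to a directional viscosity. The fit window is
#' `window_fraction` of the directional trap relaxation time (estimated
#' by equipartition along the same direction unless `kappa` is given);
#' at the default 0.1 the residual trap bias is below ~5%.
#'
#' @param traj A 3-axis trapped-bead [trajectory()].
#' @param theta,phi Direction angles (radians; polar from +z).
#' @param window_fraction Fit window as a fraction of the trap relaxation
#'   time.
#' @param kappa Optional trap stiffness along the direction (N/m).
#' @return A `directional_viscosity` with `theta`, `phi`, `D` (m^2/s),
#'   `eta` (Pa s), `eta_relative` and the fit window in lags.
#' @export
directional_viscosity <- function(traj, theta, phi, window_fraction = 0.1,
                                  kappa = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  if (n_axes(traj) != 3L)
    stop("directional viscosity needs a 3-axis trajectory")
  ctx <- traj$context
  kBT <- ctx$boltzmann_kB * ctx$temperature_T
  u <- direction_vector(theta, phi)
  proj <- as.numeric(traj$positions[, c("x", "y", "z")] %*% u)
  proj <- proj - mean(proj)
  if (is.null(kappa)) kappa <- kBT / mean(proj^2)
  tau_c <- stokes_drag(ctx) / kappa
  kmax <- floor(window_fraction * tau_c / traj$dt)
  if (kmax < 5L)
    stop(sprintf("fit window holds only %d lags (< 5); increase the frame rate or window_fraction",
                 kmax))
  n <- length(proj)
  ks <- seq_len(kmax)
  msd <- vapply(ks, function(k)
    mean((proj[(k + 1L):n] - proj[seq_len(n - k)])^2), numeric(1L))
  tau <- ks * traj$dt
  D <- sum(tau * msd) / sum(tau^2) / 2        # LS slope through origin
  eta <- kBT / (6 * pi * D * ctx$radius_a)
  structure(list(theta = theta, phi = phi, D = D, eta = eta,
                 eta_relative = eta / ctx$solvent_viscosity_eta_s,
                 window_lags = kmax, kappa = kappa),
            class = "directional_viscosity")
}

#' @export
print.directional_viscosity <- function(x, ...) {
  cat(sprintf(
    "Directional viscosity (theta = %.3f, phi = %.3f): D = %.3g m^2/s, eta = %.3g Pa s, eta_r = %.3g\n",
    x$theta, x$phi, x$D, x$eta, x$eta_relative))
  invisible(x)
}

#' Near-wall apparent-viscosity prediction
#'
#' Hydrodynamic drag on a sphere of radius `a` whose centre is a distance
#' `h` from a rigid plane wall, expressed as the apparent-to-bulk
#' viscosity ratio. Parallel to the wall the classic method-of-images
#' series is used:
#' \deqn{\eta_{app}/\eta = [1 - \tfrac{9}{16}s + \tfrac18 s^3
#'   - \tfrac{45}{256}s^4 - \tfrac1{16}s^5]^{-1}, \quad s = a/h.}
#' Perpendicular to the wall the reciprocal of the truncated Brenner
#' series is used:
#' \deqn{\eta_{app}/\eta = [1 - \tfrac98 s + \tfrac12 s^3
#'   - \tfrac{57}{100}s^4 + \tfrac15 s^5 + \tfrac{7}{200}s^{11}
#'   - \tfrac1{25}s^{12}]^{-1},}
#' a standard polynomial approximation to Brenner's exact lubrication
#' solution. Both factors tend to 1 as \eqn{h \to \infty} and the
#' perpendicular factor always exceeds the parallel one.
#'
#' @param ctx A [probe_context()].
#' @param h Bead-centre-to-wall distance (m), `> a`; may be `Inf`.
#' @param mode `"parallel"` or `"perpendicular"`.
#' @return The dimensionless drag (apparent viscosity) factor.
#' @export
faxen_prediction <- function(ctx, h, mode = c("parallel", "perpendicular")) {
  mode <- match.arg(mode)
  stopifnot(inherits(ctx, "probe_context"))
  if (any(h <= ctx$radius_a))
    stop("wall distance h must exceed the bead radius a")
  s <- ctx$radius_a / h
  denom <- if (mode == "parallel") {
    1 - 9 / 16 * s + 1 / 8 * s^3 - 45 / 256 * s^4 - 1 / 16 * s^5
  } else {
    1 - 9 / 8 * s + 1 / 2 * s^3 - 57 / 100 * s^4 + 1 / 5 * s^5 +
      7 / 200 * s^11 - 1 / 25 * s^12
  }
  1 / denom
}
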