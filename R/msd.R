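# Time-domain statistics: MSD, directional MSD, stretched bi-exponential
# MSD smoothing, NPAF and plateau variance.

msd_curve <- function(tau, values, n_pairs, dimension, context, dt) {
  stopifnot(all(diff(tau) > 0), all(tau > 0), all(values >= -1e-30),
            all(n_pairs > 0))
  structure(list(tau = tau, values = pmax(values, 0), n_pairs = n_pairs,
                 dimension = dimension, context = context, dt = dt),
            class = "msd_curve")
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("MSD curve: %d lags in [%.3g, %.3g] s, d = %d\n",
              length(x$tau), min(x$tau), max(x$tau), x$dimension))
  invisible(x)
}

#' @export
plot.msd_curve <- function(x, ...) {
  graphics::plot(x$tau, x$values, log = "xy", xlab = "lag time (s)",
                 ylab = expression(MSD ~ (m^2)), type = "b", ...)
  invisible(x)
}

# Integer lag grid: all lags, or log-spaced with n_per_decade points.
lag_grid <- function(n, scheme = c("log", "all"), n_per_decade = 16L,
                     max_lag_fraction = 0.1) {
  scheme <- match.arg(scheme)
  kmax <- max(1L, floor(n * max_lag_fraction))
  if (scheme == "all") return(seq_len(kmax))
  ks <- unique(round(10^seq(0, log10(kmax),
                            by = 1 / n_per_decade)))
  ks[ks >= 1L & ks <= kmax]
}

#' Time-averaged mean squared displacement
#'
#' \eqn{MSD(\tau) = \langle |r(t+\tau) - r(t)|^2 \rangle_t} over all
#' overlapping pairs at each lag, summed over the requested axes
#' (dimension `d` = number of axes). The default lag grid is log-spaced
#' at 16 points per decade from `dt` to 10\% of the record length, giving
#' broadband coverage without the O(N^2) cost of all lags.
#'
#' @param traj A [trajectory()] with at least 100 samples.
#' @param axes Axes to sum over (default: all present).
#' @param lag_scheme `"log"` or `"all"`.
#' @param n_per_decade Lag density for the log scheme.
#' @param max_lag_fraction Longest lag as a fraction of the record.
#' @return An `msd_curve` with lags `tau` (s), `values` (m^2), `n_pairs`,
#'   `dimension` and the probe context.
#' @export
compute_msd <- function(traj, axes = NULL, lag_scheme = c("log", "all"),
                        n_per_decade = 16L, max_lag_fraction = 0.1) {
  stopifnot(inherits(traj, "trajectory"))
  n <- length(traj$t)
  if (n < 100L) stop("MSD needs at least 100 samples")
  if (is.null(axes)) axes <- colnames(traj$positions)
  missing_ax <- setdiff(axes, colnames(traj$positions))
  if (length(missing_ax))
    stop("requested axis absent from trajectory: ",
         paste(missing_ax, collapse = ", "))
  ks <- lag_grid(n, match.arg(lag_scheme), n_per_decade, max_lag_fraction)
  pos <- traj$positions[, axes, drop = FALSE]
  vals <- vapply(ks, function(k) {
    d <- pos[(k + 1L):n, , drop = FALSE] - pos[seq_len(n - k), , drop = FALSE]
    mean(rowSums(d^2))
  }, numeric(1L))
  msd_curve(tau = ks * traj$dt, values = vals, n_pairs = n - ks,
            dimension = length(axes), context = traj$context, dt = traj$dt)
}

# Unit vector from polar angle theta (from +z) and azimuth phi.
# Components below 1e-12 are zapped so coordinate-axis directions project
# exactly onto single axes.
direction_vector <- function(theta, phi) {
  u <- c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
  u[abs(u) < 1e-12] <- 0
  nu <- sqrt(sum(u^2))
  if (nu < 1e-12) stop("direction vector has zero length")
  u / nu
}

#' Directional MSD along an arbitrary 3D axis
#'
#' Projects a 3-axis trajectory onto the unit vector
#' \eqn{u(\theta, \varphi)} (polar angle from +z, azimuth from +x) and
#' returns the 1D MSD of the projection. Along a coordinate axis this
#' reproduces [compute_msd()] on that axis exactly.
#'
#' @param traj A 3-axis [trajectory()].
#' @param theta,phi Direction angles in radians.
#' @inheritParams compute_msd
#' @return An `msd_curve` with `dimension = 1`.
#' @export
directional_msd <- function(traj, theta, phi, lag_scheme = c("log", "all"),
                            n_per_decade = 16L, max_lag_fraction = 0.1) {
  stopifnot(inherits(traj, "trajectory"))
  if (n_axes(traj) != 3L) stop("directional MSD needs a 3-axis trajectory")
  u <- direction_vector(theta, phi)
  proj <- as.numeric(traj$positions[, c("x", "y", "z")] %*% u)
  ptraj <- trajectory(traj$t, matrix(proj, ncol = 1L,
                                     dimnames = list(NULL, "x")),
                      traj$frame_rate, traj$context,
                      provenance = sprintf("projection(theta=%.3f, phi=%.3f) | %s",
                                           theta, phi, traj$provenance))
  out <- compute_msd(ptraj, axes = "x", lag_scheme = lag_scheme,
                     n_per_decade = n_per_decade,
                     max_lag_fraction = max_lag_fraction)
  out$direction <- c(theta = theta, phi = phi)
  out
}

#' Fit a stretched bi-exponential to an MSD curve
#'
#' Smooths a measured MSD with the six-parameter form
#' \deqn{MSD(\tau) = A_1 e^{-(\tau/\tau_1)^{B_1}} + A_2 e^{-(\tau/\tau_2)^{B_2}}}
#' which mitigates the noise of the finite time average before the
#' compliance/modulus conversion. Amplitude signs are unconstrained: a
#' negative \eqn{A_1} with a large \eqn{\tau_2} gives the rising,
#' saturating shape of confined motion. Fitted by weighted nonlinear
#' least squares (Levenberg--Marquardt) with weights `1/n_pairs` so the
#' abundant short lags do not dominate. When the record is much shorter
#' than \eqn{\tau_2}, \eqn{\tau_2} and \eqn{B_2} are only weakly
#' identified (any sufficiently slow decay fits); the smoothed curve and
#' the remaining parameters are still well determined.
#'
#' @param msd An `msd_curve` with at least 10 lag points.
#' @param init Optional named list overriding the automatic starting
#'   values (`A1`, `A2`, `B1`, `B2`, `tau1`, `tau2`).
#' @return A `biexp_fit` with `coefficients`, `fitted`, `residual_rms`
#'   (relative), and a `predict()` method for arbitrary lags.
#' @export
fit_stretched_biexponential <- function(msd, init = NULL) {
  stopifnot(inherits(msd, "msd_curve"))
  if (length(msd$tau) < 10L) stop("need at least 10 lag points to fit")
  tau <- msd$tau; y <- msd$values
  n <- length(y)
  biexp <- function(p, tt)
    p[["A1"]] * exp(-(tt / p[["tau1"]])^p[["B1"]]) +
    p[["A2"]] * exp(-(tt / p[["tau2"]])^p[["B2"]])
  sw <- sqrt(1 / msd$n_pairs)
  scale_y <- max(abs(y))
  if (scale_y == 0) stop("all-zero MSD cannot be fitted")
  lower <- c(A1 = -Inf, A2 = -Inf, B1 = 0.05, B2 = 0.05,
             tau1 = min(tau) / 1e3, tau2 = min(tau) / 1e3)
  upper <- c(A1 = Inf, A2 = Inf, B1 = 5, B2 = 5, tau1 = 1e15,
             tau2 = 1e15)
  run <- function(st) tryCatch(
    minpack.lm::nls.lm(
      par = st, lower = lower, upper = upper,
      fn = function(p) sw * (biexp(p, tau) - y) / scale_y,
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  # deterministic multi-start: plateau-shaped (rising toward A2) and
  # decay-shaped (A1 e^{-...} with a small slow remainder) initialisations
  rising <- y[n] >= y[1L]
  tau_scale <- if (rising) {
    i <- which(y >= (1 - exp(-1)) * y[n])
    if (length(i)) tau[i[1L]] else stats::median(tau)
  } else {
    i <- which(y <= exp(-1) * y[1L])
    if (length(i)) tau[i[1L]] else stats::median(tau)
  }
  starts <- list(
    c(A1 = y[1L] - y[n], A2 = y[n] + 0.05 * scale_y, B1 = 1, B2 = 1,
      tau1 = tau_scale, tau2 = 1e3 * max(tau)),
    c(A1 = y[1L] - y[n], A2 = y[n] + 0.05 * scale_y, B1 = 0.9, B2 = 0.9,
      tau1 = tau_scale, tau2 = 10 * max(tau)),
    c(A1 = y[1L], A2 = 0.05 * scale_y, B1 = 1, B2 = 1,
      tau1 = tau_scale, tau2 = 1e3 * max(tau)))
  if (!is.null(init)) {
    st <- starts[[1L]]
    st[names(init)] <- unlist(init)
    starts <- c(list(st), starts)
  }
  fits <- Filter(Negate(is.null), lapply(starts, run))
  if (!length(fits))
    stop("bi-exponential fit did not converge from any starting point",
         call. = FALSE)
  dev <- vapply(fits, function(f) sum(f$fvec^2), numeric(1L))
  fit <- fits[[which.min(dev)]]
  cf <- as.list(fit$par)
  fitted <- biexp(fit$par, tau)
  structure(list(coefficients = cf, tau = tau, data = y, fitted = fitted,
                 residual_rms = sqrt(mean(((fitted - y) /
                                             pmax(abs(y), 1e-300))^2)),
                 deviance = min(dev), niter = fit$niter),
            class = "biexp_fit")
}

#' @export
coef.biexp_fit <- function(object, ...) unlist(object$coefficients)

#' @export
predict.biexp_fit <- function(object, tau = object$tau, ...) {
  cf <- object$coefficients
  cf$A1 * exp(-(tau / cf$tau1)^cf$B1) + cf$A2 * exp(-(tau / cf$tau2)^cf$B2)
}

#' @export
print.biexp_fit <- function(x, ...) {
  cat("Stretched bi-exponential MSD fit\n")
  cf <- x$coefficients
  cat(sprintf("  A1 = %.4g m^2, tau1 = %.4g s, B1 = %.3g\n",
              cf$A1, cf$tau1, cf$B1))
  cat(sprintf("  A2 = %.4g m^2, tau2 = %.4g s, B2 = %.3g\n",
              cf$A2, cf$tau2, cf$B2))
  cat(sprintf("  relative residual RMS = %.3g\n", x$residual_rms))
  invisible(x)
}

npaf_curve <- function(tau, values, tau_star = NULL) {
  stopifnot(tau[1L] == 0, abs(values[1L] - 1) < 1e-12)
  structure(list(tau = tau, values = values, tau_star = tau_star),
            class = "npaf_curve")
}

#' @export
print.npaf_curve <- function(x, ...) {
  cat(sprintf("NPAF: %d lags in [0, %.3g] s%s\n", length(x$tau), max(x$tau),
              if (!is.null(x$tau_star)) " (tau* axis present)" else ""))
  invisible(x)
}

#' @export
plot.npaf_curve <- function(x, ...) {
  xx <- if (!is.null(x$tau_star)) x$tau_star else x$tau
  graphics::plot(xx, x$values, type = "l",
                 xlab = if (!is.null(x$tau_star)) "tau*" else "lag time (s)",
                 ylab = "NPAF", ...)
  graphics::abline(h = exp(-1), lty = 2)
  invisible(x)
}

#' Normalized position autocorrelation function
#'
#' \eqn{NPAF(\tau) = \langle x(t) x(t+\tau)\rangle / \langle x^2\rangle}
#' of one (detrended) axis, estimated by the unbiased time average; the
#' value at \eqn{\tau = 0} is exactly 1. For a trapped bead in a
#' Newtonian fluid the NPAF decays as \eqn{e^{-\tau/\tau_c}} with
#' \eqn{\tau_c = 6\pi a \eta / \kappa}. The direct time-domain estimator
#' is the default for transparency; the FFT path is numerically
#' equivalent and faster on long records.
#'
#' @param traj A [trajectory()] (detrend first; the mean is removed).
#' @param axis Axis name.
#' @param max_lag Longest lag in seconds (overrides `max_lag_fraction`).
#' @param max_lag_fraction Longest lag as a fraction of the record.
#' @param method `"direct"` or `"fft"`.
#' @return An `npaf_curve` with lags starting at 0.
#' @export
compute_npaf <- function(traj, axis = "x", max_lag = NULL,
                         max_lag_fraction = 0.1,
                         method = c("direct", "fft")) {
  stopifnot(inherits(traj, "trajectory"))
  method <- match.arg(method)
  x <- axis_series(traj, axis)
  x <- x - mean(x)
  n <- length(x)
  if (sum(x^2) == 0) stop("axis has zero variance; NPAF undefined")
  kmax <- if (!is.null(max_lag)) min(n - 2L, round(max_lag / traj$dt))
          else max(1L, floor(n * max_lag_fraction))
  ks <- 0:kmax
  if (method == "direct") {
    sums <- vapply(ks, function(k)
      sum(x[seq_len(n - k)] * x[(k + 1L):n]), numeric(1L))
  } else {
    m <- 2^ceiling(log2(2L * n))
    X <- stats::fft(c(x, numeric(m - n)))
    ac <- Re(stats::fft(X * Conj(X), inverse = TRUE)) / m
    sums <- ac[ks + 1L]
  }
  cc <- sums / (n - ks)                       # unbiased time average
  npaf_curve(tau = ks * traj$dt, values = cc / cc[1L])
}

#' Time-independent variance of the probe displacement
#'
#' Sum over the requested axes of the per-axis variance about the mean:
#' the \eqn{\langle r^2 \rangle} entering the plateau-modulus formula and
#' (per axis) the equipartition trap-stiffness calibration. The number of
#' axes is recorded so the dimension convention of the modulus conversion
#' can be handled downstream.
#'
#' @param traj A stationary (detrended) [trajectory()].
#' @param axes Axes to sum (default: all present).
#' @return Variance in m^2 with attributes `dimension` and `per_axis`.
#' @export
plateau_variance <- function(traj, axes = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(axes)) axes <- colnames(traj$positions)
  missing_ax <- setdiff(axes, colnames(traj$positions))
  if (length(missing_ax))
    stop("requested axis absent: ", paste(missing_ax, collapse = ", "))
  if (length(traj$t) < 100L)
    warning("fewer than 100 samples: variance estimate will be noisy")
  per <- vapply(axes, function(ax) {
    x <- traj$positions[, ax]
    mean((x - mean(x))^2)
  }, numeric(1L))
  structure(sum(per), dimension = length(axes), per_axis = per)
}
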