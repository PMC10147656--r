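#' Simulate free Brownian diffusion in a Newtonian fluid
#'
#' Positions follow unconstrained diffusion with
#' \eqn{D = k_B T / (6\pi\eta_s a)}: per-axis increments are i.i.d.
#' Gaussian with mean zero and variance \eqn{2 D \, dt}. Inertia is
#' neglected (overdamped limit), appropriate for micron beads in water at
#' frame rates of a few kHz or below.
#'
#' @param ctx A [probe_context()].
#' @param dt Time step in seconds (`1/frame_rate`).
#' @param n_steps Number of samples in the trajectory (`>= 2`).
#' @param n_axes Number of simulated axes (1--3).
#' @param seed Optional integer seed; identical seeds give bit-identical
#'   trajectories and the global RNG stream is left untouched.
#' @param eta Viscosity override (Pa s), defaulting to the solvent value.
#' @return A [trajectory()].
#' @export
simulate_free_diffusion <- function(ctx, dt, n_steps, n_axes = 1L,
                                    seed = NULL,
                                    eta = ctx$solvent_viscosity_eta_s) {
  stopifnot(inherits(ctx, "probe_context"))
  if (!is.numeric(dt) || dt <= 0) stop("'dt' must be > 0")
  if (n_steps < 2L) stop("'n_steps' must be >= 2")
  if (n_axes < 1L || n_axes > 3L) stop("'n_axes' must be 1, 2 or 3")
  D <- diffusion_coefficient(ctx, eta = eta)
  sd_inc <- sqrt(2 * D * dt)
  pos <- with_seed(seed, {
    vapply(seq_len(n_axes),
           function(i) cumsum(c(0, stats::rnorm(n_steps - 1L, 0, sd_inc))),
           numeric(n_steps))
  })
  colnames(pos) <- c("x", "y", "z")[seq_len(n_axes)]
  trajectory(t = (seq_len(n_steps) - 1L) * dt, positions = pos,
             frame_rate = 1 / dt, context = ctx,
             provenance = sprintf(
               "simulate_free_diffusion(D=%.4g m^2/s, dt=%.4g s, n=%d, seed=%s)",
               D, dt, n_steps, ifelse(is.null(seed), "NULL", seed)))
}

# Exact Ornstein-Uhlenbeck sample path: stationary start, update
# x <- x * exp(-dt/tau_c) + N(0, var_stat * (1 - exp(-2 dt/tau_c))).
# Statistics are exact at any dt (no Euler step-size bias).
ou_path <- function(n, dt, tau_c, var_stat) {
  phi <- exp(-dt / tau_c)
  innov <- c(stats::rnorm(1L, 0, sqrt(var_stat)),
             stats::rnorm(n - 1L, 0, sqrt(var_stat * (1 - phi^2))))
  as.numeric(stats::filter(innov, phi, method = "recursive"))
}

#' Simulate the residual Brownian motion of an optically trapped bead
#'
#' Each axis is an Ornstein--Uhlenbeck process with relaxation time
#' \eqn{\tau_c = \gamma/\kappa} and stationary variance
#' \eqn{k_B T/\kappa} (equipartition), discretized exactly so the sampled
#' statistics are correct for any `dt`.
#'
#' @inheritParams simulate_free_diffusion
#' @param trap A [trap_params()]; an axis with stiffness `<= 0` among the
#'   requested `axes` is an error.
#' @param axes Character vector of axes to simulate, subset of
#'   `c("x","y","z")`.
#' @param drag_factors Optional named per-axis multipliers of the Stokes
#'   drag (used by [simulate_near_wall()]).
#' @return A [trajectory()].
#' @export
simulate_trapped_bead <- function(ctx, trap, dt, n_steps, seed = NULL,
                                  axes = c("x", "y", "z"),
                                  eta = ctx$solvent_viscosity_eta_s,
                                  drag_factors = NULL) {
  stopifnot(inherits(ctx, "probe_context"), inherits(trap, "trap_params"))
  if (!is.numeric(dt) || dt <= 0) stop("'dt' must be > 0")
  if (n_steps < 2L) stop("'n_steps' must be >= 2")
  axes <- match.arg(axes, c("x", "y", "z"), several.ok = TRUE)
  gamma0 <- stokes_drag(ctx, eta = eta)
  kBT <- ctx$boltzmann_kB * ctx$temperature_T
  pos <- with_seed(seed, {
    vapply(axes, function(ax) {
      kappa <- trap[[paste0("kappa_", ax)]]
      if (kappa <= 0)
        stop(sprintf("trap stiffness along %s must be > 0 to simulate it", ax))
      fac <- if (!is.null(drag_factors) && ax %in% names(drag_factors))
        drag_factors[[ax]] else 1
      tau_c <- gamma0 * fac / kappa
      if (dt >= tau_c)
        warning(sprintf(
          "dt = %.3g s does not resolve the trap relaxation time %.3g s on %s",
          dt, tau_c, ax))
      ou_path(n_steps, dt, tau_c, kBT / kappa)
    }, numeric(n_steps))
  })
  colnames(pos) <- axes
  trajectory(t = (seq_len(n_steps) - 1L) * dt, positions = pos,
             frame_rate = 1 / dt, context = ctx,
             provenance = sprintf(
               "simulate_trapped_bead(kappa=[%s] N/m, eta=%.4g, dt=%.4g, n=%d, seed=%s)",
               paste(sprintf("%.3g", unlist(trap[paste0("kappa_", axes)])),
                     collapse = ","),
               eta, dt, n_steps, ifelse(is.null(seed), "NULL", seed)))
}

#' Simulate a bead embedded in a viscoelastic gel
#'
#' Default constitutive model is a Kelvin--Voigt element: the network
#' exerts a harmonic restoring force of stiffness
#' \eqn{\kappa_{eff} = 6\pi a G_0} against a dashpot with drag
#' \eqn{6\pi a \eta}, giving OU dynamics whose long-lag MSD plateaus at
#' \eqn{2 k_B T / (6\pi a G_0)} per axis. Optional Prony modes add
#' auxiliary relaxing strands (each a spring \eqn{6\pi a G_j} in series
#' with its own dashpot), integrated with a sub-stepped Euler scheme.
#'
#' @inheritParams simulate_trapped_bead
#' @param gel A [gel_params()]. `plateau_G0 = 0` with no Prony modes falls
#'   back to free diffusion in the gel's solvent (with a message).
#' @export
simulate_gel_bead <- function(ctx, gel, dt, n_steps, seed = NULL,
                              axes = c("x", "y")) {
  stopifnot(inherits(ctx, "probe_context"), inherits(gel, "gel_params"))
  axes <- match.arg(axes, c("x", "y", "z"), several.ok = TRUE)
  if (gel$plateau_G0 == 0 && is.null(gel$prony_modes)) {
    message("plateau_G0 = 0 and no Prony modes: simulating free diffusion")
    return(simulate_free_diffusion(ctx, dt, n_steps, n_axes = length(axes),
                                   seed = seed, eta = gel$solvent_eta))
  }
  if (!is.numeric(dt) || dt <= 0) stop("'dt' must be > 0")
  if (n_steps < 2L) stop("'n_steps' must be >= 2")
  a6p <- 6 * pi * ctx$radius_a
  kBT <- ctx$boltzmann_kB * ctx$temperature_T
  kappa <- a6p * gel$plateau_G0
  gamma <- a6p * gel$solvent_eta
  pos <- with_seed(seed, {
    if (is.null(gel$prony_modes)) {
      tau_c <- gamma / kappa
      vapply(axes, function(ax) ou_path(n_steps, dt, tau_c, kBT / kappa),
             numeric(n_steps))
    } else {
      modes <- do.call(rbind, lapply(gel$prony_modes, as.numeric))
      kj <- a6p * modes[, 1L]           # mode stiffness
      tj <- modes[, 2L]                 # mode relaxation time
      # sub-step so the stiffest coupled scale is resolved
      h <- min(dt, 0.1 * min(c(gamma / (kappa + sum(kj)), tj)))
      nsub <- max(1L, ceiling(dt / h)); h <- dt / nsub
      vapply(axes, function(ax) {
        x <- 0; u <- rep(0, length(kj)); out <- numeric(n_steps)
        noise <- stats::rnorm(n_steps * nsub, 0, sqrt(2 * kBT * h / gamma))
        idx <- 0L
        for (i in seq_len(n_steps)) {
          for (s in seq_len(nsub)) {
            idx <- idx + 1L
            f <- -kappa * x - sum(kj * (x - u))
            x <- x + f * h / gamma + noise[idx]
            u <- u + (x - u) * h / tj
          }
          out[i] <- x
        }
        out
      }, numeric(n_steps))
    }
  })
  colnames(pos) <- axes
  trajectory(t = (seq_len(n_steps) - 1L) * dt, positions = pos,
             frame_rate = 1 / dt, context = ctx,
             provenance = sprintf(
               "simulate_gel_bead(G0=%.4g Pa, eta=%.4g Pa s, modes=%d, dt=%.4g, n=%d, seed=%s)",
               gel$plateau_G0, gel$solvent_eta,
               length(gel$prony_modes), dt, n_steps,
               ifelse(is.null(seed), "NULL", seed)))
}

#' Simulate a trapped bead near a rigid plane wall
#'
#' The wall is perpendicular to z. Hydrodynamic drag along x and y is
#' multiplied by the wall-parallel correction and along z by the
#' wall-perpendicular correction from [faxen_prediction()], so the
#' perpendicular axis always sees the larger apparent viscosity. The
#' trap's stationary variance is unchanged (equipartition is drag-free);
#' only the relaxation times slow down.
#'
#' @inheritParams simulate_trapped_bead
#' @param wall A [wall_model()]; `wall_distance_h` must exceed the bead
#'   radius.
#' @export
simulate_near_wall <- function(ctx, trap, wall, dt, n_steps, seed = NULL,
                               axes = c("x", "y", "z")) {
  stopifnot(inherits(wall, "wall_model"))
  if (wall$wall_distance_h <= ctx$radius_a)
    stop("wall distance h must exceed the bead radius a")
  fac_par <- faxen_prediction(ctx, wall$wall_distance_h, "parallel")
  fac_perp <- faxen_prediction(ctx, wall$wall_distance_h, "perpendicular")
  traj <- simulate_trapped_bead(
    ctx, trap, dt, n_steps, seed = seed, axes = axes,
    drag_factors = c(x = fac_par, y = fac_par, z = fac_perp))
  traj$provenance <- sprintf(
    "simulate_near_wall(h=%.4g m, factors par=%.4g perp=%.4g) | %s",
    wall$wall_distance_h, fac_par, fac_perp, traj$provenance)
  traj
}
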