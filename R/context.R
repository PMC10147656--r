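#' @keywords internal
"_PACKAGE"

#' Boltzmann constant (J/K), CODATA exact value
#' @keywords internal
.kB <- 1.380649e-23

#' Probe and medium context
#'
#' Bundles the physical constants that convert probe motion into material
#' properties: the bead radius \eqn{a}, absolute temperature \eqn{T} and the
#' Newtonian viscosity \eqn{\eta_s} of the pure solvent. These enter the
#' Stokes drag \eqn{\gamma = 6\pi\eta_s a}, the Stokes--Einstein diffusion
#' coefficient \eqn{D = k_B T / (6\pi\eta_s a)}, the compliance prefactor
#' \eqn{k_B T/(\pi a)} and the dimensionless lag axis
#' \eqn{\tau^\ast = \kappa\tau/(6\pi a \eta_s)}.
#'
#' @param radius_a Bead radius in metres (e.g. `3e-6` for a 6 um diameter
#'   polystyrene probe).
#' @param temperature_T Absolute temperature in kelvin.
#' @param solvent_viscosity_eta_s Solvent viscosity in Pa s (water at 25 C
#'   is about `0.89e-3`).
#' @return An object of class `probe_context`.
#' @examples
#' ctx <- probe_context(radius_a = 3e-6)
#' stokes_drag(ctx)
#' diffusion_coefficient(ctx)
#' @export
probe_context <- function(radius_a,
                          temperature_T = 298.15,
                          solvent_viscosity_eta_s = 0.89e-3) {
  stopifnot(is.numeric(radius_a), length(radius_a) == 1L, is.finite(radius_a),
            is.numeric(temperature_T), length(temperature_T) == 1L,
            is.numeric(solvent_viscosity_eta_s),
            length(solvent_viscosity_eta_s) == 1L)
  if (radius_a <= 0) stop("'radius_a' must be strictly positive (metres)")
  if (temperature_T <= 0) stop("'temperature_T' must be strictly positive (K)")
  if (solvent_viscosity_eta_s <= 0)
    stop("'solvent_viscosity_eta_s' must be strictly positive (Pa s)")
  structure(
    list(radius_a = radius_a,
         temperature_T = temperature_T,
         solvent_viscosity_eta_s = solvent_viscosity_eta_s,
         boltzmann_kB = .kB),
    class = "probe_context")
}

#' Stokes drag coefficient of the probe in its solvent
#'
#' \eqn{\gamma = 6 \pi \eta_s a} in kg/s.
#' @param ctx A [probe_context()].
#' @param eta Optional viscosity override (Pa s); defaults to the solvent
#'   viscosity stored in `ctx`.
#' @export
stokes_drag <- function(ctx, eta = ctx$solvent_viscosity_eta_s) {
  stopifnot(inherits(ctx, "probe_context"))
  6 * pi * eta * ctx$radius_a
}

#' Stokes--Einstein diffusion coefficient
#'
#' \eqn{D = k_B T / (6 \pi \eta a)} in m^2/s.
#' @inheritParams stokes_drag
#' @export
diffusion_coefficient <- function(ctx, eta = ctx$solvent_viscosity_eta_s) {
  stopifnot(inherits(ctx, "probe_context"))
  ctx$boltzmann_kB * ctx$temperature_T / (6 * pi * eta * ctx$radius_a)
}

#' @export
print.probe_context <- function(x, ...) {
  cat("Probe context\n")
  cat(sprintf("  bead radius a      : %.3g m\n", x$radius_a))
  cat(sprintf("  temperature T      : %.4g K\n", x$temperature_T))
  cat(sprintf("  solvent viscosity  : %.3g Pa s\n", x$solvent_viscosity_eta_s))
  cat(sprintf("  Stokes drag gamma  : %.3g kg/s\n", stokes_drag(x)))
  cat(sprintf("  diffusion coeff D  : %.3g m^2/s\n", diffusion_coefficient(x)))
  invisible(x)
}

#' Optical trap stiffness parameters
#'
#' Per-axis harmonic trap stiffness in N/m. Optical traps formed by a single
#' focused beam are typically ~5x weaker axially than laterally, so the
#' axial default is `kappa_x / 5`.
#'
#' @param kappa_x,kappa_y,kappa_z Trap stiffness along x, y, z (N/m), each
#'   `>= 0`; at least one must be positive.
#' @return An object of class `trap_params`.
#' @export
trap_params <- function(kappa_x, kappa_y = kappa_x, kappa_z = kappa_x / 5) {
  k <- c(kappa_x = kappa_x, kappa_y = kappa_y, kappa_z = kappa_z)
  if (any(!is.finite(k)) || any(k < 0))
    stop("trap stiffnesses must be finite and >= 0 (N/m)")
  if (all(k == 0)) stop("at least one trap stiffness must be > 0")
  structure(as.list(k), class = "trap_params")
}

#' @export
print.trap_params <- function(x, ...) {
  cat(sprintf("Trap stiffness (N/m): x = %.3g, y = %.3g, z = %.3g\n",
              x$kappa_x, x$kappa_y, x$kappa_z))
  invisible(x)
}

#' Gel constitutive parameters for the bead-in-gel simulator
#'
#' A Kelvin--Voigt element (elastic plateau `plateau_G0` in parallel with a
#' dashpot of viscosity `solvent_eta`) is the default network model; an
#' optional Prony series adds relaxing modes, each a (modulus, relaxation
#' time) pair.
#'
#' @param plateau_G0 Low-frequency elastic plateau modulus (Pa), `>= 0`.
#' @param solvent_eta Viscous drag term of the network (Pa s), `> 0`.
#' @param prony_modes Optional list of `c(G = , tau = )` pairs with
#'   positive moduli (Pa) and relaxation times (s).
#' @return An object of class `gel_params`.
#' @export
gel_params <- function(plateau_G0, solvent_eta, prony_modes = NULL) {
  stopifnot(is.numeric(plateau_G0), length(plateau_G0) == 1L,
            is.numeric(solvent_eta), length(solvent_eta) == 1L)
  if (!is.finite(plateau_G0) || plateau_G0 < 0)
    stop("'plateau_G0' must be finite and >= 0 (Pa)")
  if (!is.finite(solvent_eta) || solvent_eta <= 0)
    stop("'solvent_eta' must be strictly positive (Pa s)")
  if (!is.null(prony_modes)) {
    for (m in prony_modes) {
      if (length(m) != 2L || any(!is.finite(m)) || any(m <= 0))
        stop("each Prony mode must be a positive (modulus, relaxation time) pair")
    }
  }
  structure(list(plateau_G0 = plateau_G0, solvent_eta = solvent_eta,
                 prony_modes = prony_modes),
            class = "gel_params")
}

#' Plane-wall hydrodynamic model
#'
#' Describes a rigid plane wall a distance `wall_distance_h` from the bead
#' centre; `mode` selects the drag correction applied to motion parallel or
#' perpendicular to the wall.
#'
#' @param wall_distance_h Bead-centre-to-wall distance (m), must exceed the
#'   bead radius.
#' @param mode `"parallel"` or `"perpendicular"`.
#' @return An object of class `wall_model`.
#' @export
wall_model <- function(wall_distance_h, mode = c("parallel", "perpendicular")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(wall_distance_h), length(wall_distance_h) == 1L)
  if (!is.finite(wall_distance_h) && !is.infinite(wall_distance_h))
    stop("'wall_distance_h' must be numeric")
  if (wall_distance_h <= 0) stop("'wall_distance_h' must be positive (m)")
  structure(list(wall_distance_h = wall_distance_h, mode = mode),
            class = "wall_model")
}

# Evaluate code with a private RNG stream so simulators never leak global
# RNG state; seed = NULL draws from the current stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}
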