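# microrheo

Passive particle-tracking microrheology in R: from transmission videos of
micron-scale probe beads (or simulated trajectories) to broadband
viscoelastic moduli, plateau stiffness, trap-calibrated relative
viscosity, and angle-resolved viscosity maps near surfaces.

The package is aimed at users of combined imaging/optical-tweezers
instruments who need the full analysis chain for thermal-motion
rheometry in soft biological materials — hydrogels, pericellular matrix,
nutrient media around spheroids — together with a Brownian-dynamics
simulator that provides exact ground truth for every stage of that
chain.

## What it computes

A probe of radius *a* embedded in a material at temperature *T* performs
thermal motion whose time-averaged mean squared displacement
MSD(τ) encodes the material's mechanics:

- **Creep compliance** (generalized Stokes–Einstein relation):
  MSD(τ) = (k_B T / π a) · J(τ)
- **Complex shear modulus** via the Fourier transform of the
  piecewise-linear interpolant of the sampled compliance:
  G\*(ω) = 1 / (iω Ĵ(ω)), evaluated as G\*(ω) = iω / D(ω) where D(ω) is
  the analytic transform of the interpolant's second derivative (no
  functional form assumed, accurate across the sampled band).
- **Plateau modulus** of a gel directly from the confined-position
  variance: G₀′ = k_B T / (π a ⟨r²⟩) (with a documented
  dimension-corrected alternative G₀′ = d·k_B T / (6 π a ⟨r²⟩)).
- **Trap stiffness** by equipartition: κ = k_B T / ⟨x²⟩.
- **Relative viscosity at a glance**: plotted against the dimensionless
  lag τ\* = κτ/(6π a η_s), the normalized position autocorrelation
  function (NPAF) of a trapped bead in a Newtonian fluid crosses e⁻¹ at
  τ\* = η/η_s.
- **Angle-resolved viscosity**: early-lag directional MSD slopes give
  D(θ,φ) by Fick's law and η(θ,φ) = k_B T/(6π D a) by Stokes–Einstein,
  with near-wall drag predictions (Faxén parallel series, Brenner-type
  perpendicular series) for comparison.

Around this core sit: exact Ornstein–Uhlenbeck simulators for free,
trapped, gel-embedded and near-wall beads; a transmission-contrast
renderer (including 3×3-tiled nine-plane multiplane frames); a tracker
using two-level multi-Otsu centre-of-mass localization in *xy* and a
sharpness-calibration lookup in *z*; trajectory detrending and a
spectral notch filter for single-frequency instrument noise; and exact
point-to-triangle-mesh distances for relating per-probe rheology to cell
cluster geometry.

## Worked example

Optically trapped 6 µm bead in water, 300,000 frames at 300 Hz, NPAF
viscometry; then a bead in a 5 Pa gel at 5 kHz:

```r
library(microrheo)
ctx  <- probe_context(radius_a = 3e-6)        # 6 um bead, water, 25 C
trap <- trap_params(3.2e-7, 3.2e-7, 6.7e-8)   # N/m; z ~5x weaker
traj <- simulate_trapped_bead(ctx, trap, dt = 1/300, n_steps = 3e5, seed = 42)
traj <- detrend(traj)$trajectory
kappa <- trap_stiffness_equipartition(traj, "x")
np    <- compute_npaf(traj, "x", max_lag = 2, method = "fft")
relative_viscosity_npaf(np, kappa, ctx)
#> NPAF relative viscosity: eta_r = 0.9754 (kappa = 3.17e-07 N/m)

gel <- simulate_gel_bead(ctx, gel_params(5, 0.01), dt = 1/5000,
                         n_steps = 1.5e5, seed = 42)
plateau_modulus(plateau_variance(gel), ctx, "dimension_corrected")
#> G0' = 4.984 Pa (from <r^2> = 2.92e-17 m^2, d = 2, dimension_corrected convention)
```

The recovered relative viscosity is 1 within estimator noise (water in
water) and the plateau modulus returns the injected 5 Pa within a few
percent; `compliance_to_modulus()` on the same trajectory gives the full
G′(ω), G″(ω) spectra with the rubbery plateau at low frequency.

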