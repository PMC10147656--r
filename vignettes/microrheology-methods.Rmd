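---
title: "Passive microrheology from probe trajectories: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Passive microrheology from probe trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microrheo)
```

# The physical model

A spherical probe of radius $a$ suspended in a material at temperature
$T$ is continuously kicked by thermal collisions. In the overdamped
limit (micron-scale beads in aqueous media at frame rates of a few kHz
or below, where inertia relaxes in microseconds) its motion is fully
characterised by statistics of the position trace, and those statistics
encode the material's mechanics:

* In a **Newtonian fluid** the bead diffuses freely with
  $D = k_B T / (6\pi\eta a)$; the one-dimensional MSD is $2D\tau$.
* In an **optical trap** each axis obeys an Ornstein–Uhlenbeck (OU)
  process: restoring force $-\kappa x$ against Stokes drag
  $\gamma = 6\pi\eta a$, relaxation time $\tau_c = \gamma/\kappa$,
  stationary variance $k_B T/\kappa$ (equipartition), MSD
  $2\frac{k_BT}{\kappa}(1 - e^{-\tau/\tau_c})$ and normalized position
  autocorrelation $e^{-\tau/\tau_c}$.
* In a **gel** the polymer network confines the bead. We model the
  network as a Kelvin–Voigt element: spring $6\pi a G_0$ in parallel
  with dashpot $6\pi a \eta$, again giving OU dynamics whose long-lag
  MSD plateaus at $2 k_B T/(6\pi a G_0)$ per axis. Optional Prony modes
  (spring $6\pi a G_j$ in series with its own dashpot, relaxation time
  $\tau_j$) add intermediate relaxations.
* **Near a rigid wall** the drag becomes anisotropic. Parallel to the
  wall we use the classical method-of-images series
  $\left[1 - \tfrac{9}{16}s + \tfrac18 s^3 - \tfrac{45}{256}s^4 -
  \tfrac1{16}s^5\right]^{-1}$ with $s = a/h$; perpendicular we use the
  reciprocal of a truncated Brenner-series polynomial (orders up to
  $s^{12}$, coefficients in `faxen_prediction()`), a standard
  approximation to the exact lubrication solution that diverges at
  contact and always exceeds the parallel factor.

## From motion statistics to material functions

The generalized Stokes–Einstein relation links the time-averaged MSD to
the creep compliance, $MSD(\tau) = \frac{k_B T}{\pi a} J(\tau)$, and the
complex shear modulus follows from the Fourier transform of the
compliance, $G^\ast(\omega) = 1/(i\omega\hat J(\omega))$. We evaluate
$\hat J$ analytically for the piecewise-linear interpolant of the
sampled $J(t_k)$, extended from $(0, J_0)$ below the first sample and
linearly at a declared terminal slope beyond the last. The resulting sum
is the transform of the interpolant's second derivative and equals
$(i\omega)^2\hat J(\omega)$, so the modulus is computed as
$G^\ast(\omega) = i\omega / D(\omega)$. This data-driven transform makes
no constitutive assumption and is exact for the interpolant; its only
error is the interpolation error of the time grid (see *Numerical
choices*).

Two shortcut estimators complement the broadband pipeline:

* the **plateau modulus** directly from the stationary variance,
  $G_0' = k_B T / (\pi a \langle r^2\rangle)$; and
* **NPAF viscometry**: on the dimensionless lag axis
  $\tau^\ast = \kappa\tau/(6\pi a \eta_s)$ a Newtonian medium of
  viscosity $\eta$ gives $NPAF = e^{-\tau^\ast \eta_s/\eta}$, so the
  abscissa of the $e^{-1}$ intercept *is* the relative viscosity
  $\eta/\eta_s$.

For directions not aligned with the trap axes, the large axial/lateral
stiffness anisotropy distorts NPAF-based estimates, so angle-resolved
viscosity instead uses the early-lag directional MSD: at lags well below
the trap relaxation time the bead moves as if untrapped, Fick's law
$MSD(\tau) = 2D\tau$ applies along any unit vector, and
$\eta(\theta,\varphi) = k_B T / (6\pi D a)$.

# The dimension convention

The $k_B T/(\pi a)$ prefactor of the MSD–compliance relation corresponds
to a three-dimensional MSD, while gel recordings are typically
two-dimensional and the variance entering $G_0'$ may be per-axis or
summed. Both conventions are therefore implemented and recorded in every
result object:

* `"paper"` (default): the literal formulas above, for reproducing
  published analyses;
* `"dimension_corrected"`: $J = \frac{3\pi a}{d\,k_B T} MSD_d$ and
  $G_0' = \frac{d\,k_B T}{6\pi a \langle r^2\rangle}$ for a $d$-axis
  measurement.

The corrected pair is internally consistent: inverting the per-axis
equipartition variance $k_B T/(6\pi a G_0)$ of the Kelvin–Voigt model
recovers the injected $G_0$ exactly, and the low-frequency limit of
$G'(\omega)$ from the full pipeline agrees with the variance route. The
literal convention reproduces published numbers but the two routes then
differ by a fixed factor; reports always carry the convention used.

# Estimators and their tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| lag grid | log, 16 points/decade, up to 10% of record | – | MSD/NPAF lags; broadband coverage without $O(N^2)$ cost |
| frequency grid | log, 10 points/decade, $\omega \in [2\pi/t_{max}, \pi/t_{min}]$ | rad/s | modulus evaluation band |
| terminal slope | 0 (gel) or last-decade fit (fluid) | 1/(Pa s) | compliance extrapolation beyond the record |
| `amplitude_threshold` | $2\times10^{-10}$ | m | minimum spectral line amplitude removed by the notch filter |
| peak width / prominence | ≤ 3 bins, ≥ 5× running median of 50-bin neighbourhood | – | what counts as a "single-frequency" line |
| `window_fraction` | 0.1 | of $\tau_c$ | directional-MSD fit window |
| detrend model | linear | – | drift removal before stationary statistics |

**MSD smoothing.** Measured MSDs are noisy at short lags (finite
record) and the package fits the stretched bi-exponential
$A_1 e^{-(\tau/\tau_1)^{B_1}} + A_2 e^{-(\tau/\tau_2)^{B_2}}$ before the
compliance conversion. Amplitude signs are unconstrained — a negative
$A_1$ yields the rising, saturating shape of confined motion. The fit is
weighted nonlinear least squares (Levenberg–Marquardt on box-bounded
parameters, deterministic multi-start from plateau-shaped and
decay-shaped initialisations, best weighted deviance kept) with weights
$1/n_{pairs}$ so the dense short-lag points do not dominate. When the
record is much shorter than $\tau_2$, $\tau_2$ and $B_2$ are only weakly
identified — any sufficiently slow second term fits — and only the
smoothed curve and the remaining parameters should be interpreted.

**NPAF crossing.** The $e^{-1}$ intercept is located on the *first
downward* crossing with log-linear interpolation between the bracketing
samples: exact for exponential decay, and robust to the re-crossings
that estimator noise produces at long lags. The statistical error of the
crossing scales like $e\sqrt{2\tau_c/T_{record}}$, which is why
viscometry records are long (minutes); the instrument-scale settings
(300,000 frames at 300 Hz) put it at a few percent per axis.

**Directional viscosity.** The linear Fick fit over the window
$[0, 0.1\,\tau_c]$ carries a deterministic trap bias below about 5%
(the OU MSD curves away from $2D\tau$); shrinking the window trades this
bias against slope noise. The window is expressed in units of the
measured directional relaxation time (equipartition stiffness along the
same direction), so it adapts to trap anisotropy.

# Tracking

**Lateral.** Transmission illumination renders the bead as a dark disk
on a bright background. Intensities are partitioned into three classes
by two-level multi-Otsu thresholding; the bead mask is the darkest
class, reduced to its dominant connected component (two comparable
components flag the frame as failed rather than guessing). The position
is an intensity-weighted centre of mass, refined by an
absorbance-weighted centroid over a circular window centred on the mask
centroid — the refinement weights are independent of the Otsu
thresholds, which removes threshold-noise coupling and reaches
~0.02 px RMS at a contrast-to-noise ratio of 20. A symmetric 3×3
pre-smoothing damps read noise without bias (the kernel is symmetric,
preserving exact whole-pixel shift equivariance). Pixel convention:
0-based indices, pixel centres at integers.

**Axial.** Nine-plane multiplane frames (3×3 tile, row-major, plane
label $3(row-1)+(col-1)-4$, spacing $\Delta z$) are split losslessly;
each sub-image gets a sharpness score. The metric is normalized
squared-gradient energy (Tenengrad): translation-insensitive, invariant
to global intensity scale, zero on structureless images, and strictly
decreasing with defocus blur over the calibration range — any metric
with these properties would serve; this one is standard and testable. A
per-bead calibration sweep tabulates the nine normalized
sharpness-vs-$z$ profiles; the valid range is the largest interval on
which the sharpness-weighted plane centroid is strictly monotone
(invertibility). Localization minimizes the sum of squared differences
between the frame's nine-plane signature and the interpolated profiles,
with parabolic sub-grid refinement; out-of-range matches are flagged and
dropped. Dropped frames are recorded and never interpolated —
interpolation biases the MSD — and when drops occur the longest
contiguous run of successful frames is analysed.

# The noise filter

Laboratory interference appears as sharp spectral peaks of essentially
single-frequency width. Per axis, the amplitude spectrum is scanned for
contiguous groups of at most 3 FFT bins exceeding both the absolute
threshold ($2\times10^{-10}$ m single-sided amplitude) and 5× the
running median of their 50-bin neighbourhood; qualifying bins are scaled
down to the local background level (zeroing would delete legitimate
Brownian power) and the removal is reported. The filter is idempotent
and, on clean data, a near-identity (MSD change below 1% at all lags).
One physical caveat the tests reflect: a line can only be *detected*
where the Brownian background per bin is well below the line amplitude.
For a weakly trapped bead in water the position spectrum at tens of Hz
is itself of order $10^{-10}$ m per bin, so the filter fixtures use
gel-embedded recordings at 5 kHz — the regime the threshold was designed
for — where lines at hundreds of Hz sit on a background an order of
magnitude smaller.

# The simulators as ground truth

All simulators use the **exact OU discretization**
($x \leftarrow x e^{-\Delta t/\tau_c} + \mathcal N(0, \sigma^2(1 -
e^{-2\Delta t/\tau_c}))$, stationary start) rather than Euler–Maruyama,
so sampled statistics are correct at any step size and oracle tests
carry no step-size bias. Seeds are explicit arguments; the global RNG
stream is saved and restored. Prony-mode gels are the one exception:
the coupled bead–strand system is integrated with a sub-stepped Euler
scheme (step bounded by a tenth of the fastest time scale), which is
documented as approximate.

The renderer draws a dark disk of the bead's physical diameter whose
edge profile is an error function of radius, with width growing linearly
with defocus, plus optional Gaussian read noise and Poisson shot noise.
It emulates transmission contrast, defocus blur, and the nine-plane
geometry; it does **not** model diffraction rings, spherical aberration,
depth-dependent magnification, motion blur within an exposure, or
bead–bead overlap. Passing render-and-recover tests therefore
demonstrates correctness of the estimators under the stated image model,
not robustness to every optical artifact of real data. Similarly the
simulators omit hydrodynamic memory (Basset) forces and bead–bead
interactions; published observations of fast sedimentation
(tens of µm/s for 3 µm-radius beads, versus ~1 µm/s from Stokes
settling of polystyrene in water) are noted but not modelled — the
trapped-bead simulators hold the probe regardless.

# Numerical choices

* **Transform accuracy.** The compliance transform is exact for the
  piecewise-linear interpolant; at 16 points/decade the interpolation
  error is invisible in $|G^\ast|$ but extracting the *minority*
  component (e.g. $G'$ where $G'' = \omega\eta$ dominates) amplifies
  phase error. Closed-form oracle checks therefore sample analytic
  compliances at 64 points/decade, where both components agree with the
  oracles to well under 5% across the central band.
* **Terminal slope.** Gels default to slope 0 (elastic plateau); fluids
  to the last-decade linear fit of $J(t)$. The choice is declared in the
  compliance object because the low-frequency band depends on it.
* **Degenerate inputs.** Zero-variance axes are errors for NPAF and
  trap calibration; zero-contrast frames are localization failures, not
  positions; meshes are cleaned of zero-area faces; $G_0 = 0$ with no
  modes falls back to free diffusion with a message.
* **Interior probes.** Mesh distances are unsigned with a ray-parity
  interior flag (fixed non-axis-aligned ray direction avoids edge
  grazing for generic meshes).
* **Tie-breaks.** The multi-Otsu search takes the first maximizing
  threshold pair; the NPAF crossing takes the first bracketing pair;
  nearest-cluster ties take the first minimum.

# Problem sizes in the test suite

Test fixtures use the instrument-scale acquisition settings where they
are cheap (3×10⁵ frames at 300 Hz for trap statistics) and scaled-down
versions elsewhere (1.5×10⁵ frames at 5 kHz for gel plateaus; 2,500
rendered frames for end-to-end tracking; 10⁵ surface samples for the
brute-force mesh oracle). These sizes keep each check to seconds while
leaving estimator noise several times smaller than the asserted
tolerances.

# Known limitations

* Axial localization assumes one bead per region of interest and a
  per-bead calibration covering the excursion range; variances below
  the ~30 nm axial precision floor (stiff gels) are not resolvable in
  $z$, matching the instrument experience.
* The NPAF method assumes a Newtonian medium and principal-axis
  alignment; use the directional route otherwise.
* The literal plateau/compliance convention reproduces published
  numbers but is internally inconsistent for $d \ne 3$; the corrected
  convention is recommended for simulation round-trips.
* No active (driven-probe) microrheology, no two-point microrheology,
  no Kramers–Kronig enforcement.
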