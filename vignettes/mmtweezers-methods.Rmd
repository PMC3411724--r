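---
title: "Models and methods behind mmtweezers"
author: "mmtweezers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mmtweezers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmtweezers)
```

# Scope

`mmtweezers` implements the quantitative machinery of multiplexed magnetic
tweezers (MMT) on DNA-bead tethers: the magnetostatic model of the force
field applied by the external magnet pair, worm-like-chain (WLC) elasticity,
an overdamped Langevin simulator of the tethered bead, the bicircular
(Limaçon) analysis of magnet-rotation measurements, and the high-throughput
elasticity-characterization pipeline, together with a synthetic-experiment
generator that stands in for laboratory data. This vignette explains the
models, the defaults, and the design decisions a user should know about.

# The magnetostatic model

## Charge sheets

The field of a uniformly magnetized block can be written as the Coulomb
field of fictitious magnetic surface charge on the two faces normal to the
magnetization. Each magnet of the vertically magnetized, antiparallel pair
therefore contributes two uniformly charged rectangles (top and bottom
face, charge density $\pm B_r$), and the total field is the signed sum of
four sheet fields. The field of a uniformly charged rectangle has an exact
closed form (arctan terms for the normal component, log terms in-plane), so
no spatial discretization is involved; the test suite validates the closed
form against brute-force 2D quadrature of the Coulomb kernel.

## Geometry defaults and the bead depth

The magnet blocks are 5 mm cubes with remanent field 1.4 T and a 2 mm gap —
an assumed configuration, since only the gap is part of the measured record
for this instrument class; everything is configurable through
`magnet_assembly()`. `Z_mag`, the force-control variable, is the distance
from the magnet bottom face to the *top surface of the flow cell*. The bead
is not at that surface: the top cover glass (0.17 mm) and the channel
(0.23 mm) put it `bead_depth = 0.4` mm lower. This matters close to the
magnets: with the bead depth included, the model reproduces the measured
force-angle benchmarks (27.7° at the field-of-view edge with the magnets
touching the flow cell, 3.4° at `Z_mag` = 1 mm) essentially exactly, while
ignoring it predicts 75° and 6.4°.

A consequence of the bead depth is that the on-axis force is *not*
monotone in `Z_mag` below about 0.7 mm: the bead then sits in the nearly
uniform field region below the gap, where the gradient is small. All
quantitative force work here uses `Z_mag` of at least 1 mm, where the force is
monotone and close to exponential in height.

## Bead magnetization and the force convention

The induced moment follows a Langevin curve,
$m(B) = V M_\mathrm{sat} \left[\coth(B/B_0) - B_0/B\right]$, with the
vendor parameters $M_\mathrm{sat} = 43.3$ kA/m and $B_0 = 12$ mT for MyOne
beads (radius 0.525 µm). Two force conventions are implemented:

* `m_gradB` (default): $F = m(|B|)\,\nabla|B|$, the energy-consistent
  force on an induced Langevin moment ($U = -\int m\,dB$);
* `grad_mB`: $F = \nabla\!\left(m(|B|)\,|B|\right)$.

They agree where the bead is saturated and differ in the weak-field tail.
The single-exponential description of the on-axis force over
`Z_mag` = 1–8 mm is distinctly better under `grad_mB` (decay length
1.87 mm, maximum relative error 6.9%), so the decay-length analysis uses
that convention and records it in the fit metadata; field maps and angles
are reported under the default convention (at `Z_mag` ≥ 1 mm the choice is
immaterial at the benchmark precision). The force gradient is taken by
central differences with a 1 µm step; halving the step moves the force by
less than 0.01%.

The absolute force scale deserves a caveat: with the assumed geometry the
model gives about 4 pN on the axis at `Z_mag` = 1 mm. Per-bead calibration
factors in real runs are of the same order but not identical, which is
exactly why the pipeline calibrates $F_0$ per bead rather than trusting the
field model. Error metrics quoted in force units (e.g. the maximum absolute
error of the exponential fit) inherit this scale.

# WLC elasticity

`wlc_force()` implements the interpolation formula with the seven-parameter
polynomial correction of Bouchiat and co-workers
($a_2 \dots a_7$ = −0.5164228, −2.737418, 16.07497, −38.87607, 39.49944,
−14.17718); the uncorrected interpolation formula is available via
`correction = FALSE`. The stretching energy `wlc_energy()` is the *exact*
antiderivative of the force law rather than a numerical quadrature, so
`dE/dl = F` holds to machine precision and the energy model used in fitting
is fast enough to sit inside a nonlinear optimizer. The inverse
`wlc_extension_at_force()` is a bracketed root solve. Units: contour length
in µm, persistence length in nm, force in pN, energy in units of
$k_\mathrm{B}T$ (default temperature 295.15 K, i.e. 22 °C).

# Tether dynamics

`simulate_trace()` integrates the overdamped equation of motion

$$\gamma_\perp(h)\,\frac{dz}{dt} = F_\mathrm{mag}(t) - F_\mathrm{WLC}(z)
  + \sqrt{2 k_\mathrm{B} T\, \gamma_\perp}\,\xi(t)$$

by Euler–Maruyama, with Faxén's wall correction for perpendicular motion,
$\gamma_\perp = 6\pi\eta R/\left[1 - \tfrac{9}{8}(R/h) +
\tfrac12(R/h)^3\right]$, evaluated at the bead-centre height
$h = z + R$, a reflecting boundary at the surface, and viscosity 0.955
mPa·s (water at 22 °C). The attachment offset affects only the measurement
transform, not the hydrodynamics — a simplification, since strictly the
wall constraint acts on the bead bottom.

The time step defaults to `dt = "auto"`: the smaller of $10^{-4}$ s and a
tenth of the bead relaxation time $\gamma/k$ at the stiffest point of the
protocol, so the stability condition holds by construction; an explicit
`dt` is checked against the same condition and the integrator aborts if a
single step ever exceeds 5% of the contour length. Halving the automatic
step changes a deterministic ramp trajectory by well under 0.1%.

The camera model applies boxcar exposure averaging over each frame period
(50 Hz default) and then additive Gaussian tracking noise
($\sigma_z$ = 12 nm, $\sigma_{xy}$ = 2.2 nm). Exposure averaging is a real
physical effect with consequences: it attenuates the observed fluctuation
variance (motion blur), which the force calibration must undo (below).

Transverse traces for calibration are simulated as an independent
Ornstein–Uhlenbeck pendulum mode with stiffness $F/(l_\mathrm{ext} + R)$ —
the lever arm includes the bead radius because the restoring torque acts
about the anchor point at the surface while the tracked coordinate is the
bead centre — and the parallel-motion variant of the wall-corrected drag.

# Rotation analysis

A tether that is off the magnet rotation axis precesses at twice the magnet
rotation frequency (half a turn of an antiparallel pair restores the same
field magnitude pattern), while an eccentric DNA attachment point adds a
circular component at the rotation frequency itself. The combined pattern,

$$x(t) = x_0 + R_\mathrm{att}\cos(\omega t + \varphi_\mathrm{att})
             + R_\mathrm{prec}\cos(2\omega t + \varphi_\mathrm{prec}),$$

with the sine analogue in $y$, is a Limaçon; it self-intersects exactly
when $2R_\mathrm{prec} > R_\mathrm{att} > 0$. Because both frequencies are
known from the magnet drive, `fit_limacon()` is a *linear* least-squares
projection onto quadrature amplitudes shared between the x- and
y-equations — no nonlinear optimization, no starting values, radii
non-negative by construction (sign flips become phase shifts of π). The
phases are left free rather than locked to a roulette relation, since the
experimental phase relation depends on magnet orientation and attachment
azimuth.

The attachment radius converts to a hidden tether length by sphere
geometry, $A = R - \sqrt{R^2 - R_\mathrm{att}^2}$. For DNA bound uniformly
over the bead surface with the bead free to rotate about its horizontal
magnetic easy axis, the offset density is

$$p(A) = \frac{1 - A/R}{R\sqrt{1 - (1 - A/R)^2}},$$

with closed-form CDF $P(A \le a) = \sqrt{1 - (1 - a/R)^2}$ used for
inverse-CDF sampling. The density is re-derived from the geometric
construction (offset $A = R(1 - \sin\alpha)$ with $\alpha$ the angle of
the attachment direction to the easy axis) and verified against
Monte-Carlo sphere sampling in the tests, since its printed form is not
machine-readable in the source material this package draws on.

`predict_precession_radius()` uses small-angle pendulum geometry,
$R_\mathrm{prec} = (l_\mathrm{ext} + R)\tan\alpha$, with the force angle
$\alpha$ from the field model; the lever arm choice (extension plus bead
radius) is an interpretation, documented here because no closed formula
for this prediction is part of the measured record.

# The characterization pipeline

Per bead, the protocol is: (i) surface reference — the lowest height in a
long zero-force recording is the apparent surface contact level and is
subtracted (a shape heuristic warns when the trace never piles up against
its minimum, as a tethered bead under residual tension would not);
(ii) attachment offset from the Limaçon fit of the rotation measurement,
applied as $l_\mathrm{ext} = l_\mathrm{meas} + A$; (iii) force calibration
at three magnet heights from transverse fluctuations by equipartition,
$F = k_\mathrm{B}T\,(l_\mathrm{ext}+R)/\mathrm{var}(x)$, with the motion
blur of the exposure window inverted through the known OU attenuation
factor $2(\varphi - 1 + e^{-\varphi})/\varphi^2$, $\varphi = k T_\mathrm{exp}/\gamma$
(a one-dimensional root solve; the additive tracking noise of 2.2 nm is
negligible against the >100 nm pendulum fluctuations and is not
subtracted); (iv) a log-linear fit with fixed decay length
(`l_dec` = 1.54 mm, the experimentally measured value) turns the three
calibrations into the bead-specific scale $F_0$; (v) the force ramp is
converted to a force-extension curve, restricted to calibrated forces of
0.01–2 pN, *reordered* to monotone extension, and integrated
trapezoidally into an energy-extension curve; (vi) nonlinear least squares
of $E(l) = E_\mathrm{WLC}(l; L_p, L_c) + E_0$ yields the persistence and
contour lengths. The free offset $E_0$ absorbs the unknown lower
integration bound. Fits with $L_p$ < 28 nm are classified as multiply
tethered and excluded from ensemble statistics.

Reordering before integration is what makes the energy curve smooth:
thermal excursions in extension get re-assigned to their proper place on
the curve, and the tests verify both that the reordered energy curve is
less rough than the unordered one and that the energy curve is smoother
than the force curve it came from.

Equipartition replaces full power-spectral-density fitting for force
calibration. For simulated data this is adequate by construction (the
simulator's transverse mode is exactly the OU process the blur correction
assumes); for real data a PSD fit would additionally diagnose drift and
aliasing, which is out of scope here.

# The synthetic-experiment generator

`ensemble_config()` fixes the study conditions: a 300 × 400 µm field of
view, minimum bead separation 15 µm (rejection-sampled placement; 60 beads
at full density place successfully), 50 Hz acquisition, tracking noise as
above, contour-length groups 0.748/2.482/4.046/6.834 µm (2.2/7.3/11.9/20.1
kb at 0.34 nm per base pair), true persistence length 50 nm, log-normal
per-bead force scale with mean 6.0 pN and relative SD 0.11, measured decay
length 1.54 mm, and protocol durations of 25 s (hold), 130 s (zero-force),
20 s per calibration height and a 1→8 mm ramp at 0.1 mm/s. The apparent
surface height in raw traces is 0.3 µm — an arbitrary but realistic offset
that the surface-reference step must remove. Each bead derives a
deterministic sub-seed from the master seed, so individual trajectories do
not depend on ensemble size or step selection.

The generated traces use the measured-height convention
($z_\mathrm{meas} = \max(l_\mathrm{real} - A, 0) + \mathrm{offset}$): what
the generator writes is what a tracking pipeline would report, and the
analysis chain has to undo both corruptions.

What the generator does *not* emulate: bead-tracking artefacts beyond
additive Gaussian noise, thermal drift of the instrument, torsional
constraint, bead–bead magnetic interactions, force heterogeneity across
the field of view during a single ramp (each bead's ramp uses its own
$F_0$ but a common exponential shape), and multiply tethered beads (the
28 nm classifier is exercised with stiff synthetic WLC curves instead).
Passing tests therefore demonstrate the internal consistency of the
analysis chain under realistic noise, not robustness to every artefact of
real recordings.

# Numerical choices and problem sizes

* Noise-free pipeline validation uses one bead per length group; with
  thermal noise, trend checks use six beads per group and the force-scale
  spread check uses 120 beads (calibration steps only). These sizes keep
  the full test suite in the minutes range while leaving the Monte-Carlo
  assertions well-powered.
* The Limaçon fit accuracy checks use 100 noise seeds (4 turns at 50 Hz,
  2.2 nm noise): radii recover within 3 nm with bias below 0.5 nm.
* The offset-density Monte-Carlo uses $10^6$ sphere samples
  (Kolmogorov–Smirnov distance below 0.002).
* The drag-budget ramp integrates about $5.7\times10^6$ Euler steps in
  compiled code (seconds).

# Known limitations

* The magnet dimensions and remanence are assumptions; quantities that
  depend on the absolute force scale (not on shape or geometry ratios)
  inherit an uncertainty of order tens of percent.
* The attachment-offset bias of the fitted persistence length depends
  strongly on the force window of the fit (from ~4 nm at 0.01–0.5 pN to
  ~20 nm at 0.1–2 pN for a 0.8 µm molecule with maximal offset); the
  pipeline's standard window 0.01–2 pN gives 16.5 nm. Comparisons of this
  number across analyses are only meaningful with the window held fixed.
* Only vertical dynamics are simulated for force-response work; the
  transverse mode is an independent linear pendulum, valid for small force
  angles.
* Torque, twist elasticity and overstretching are out of scope (tethers
  are torsionally unconstrained).
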