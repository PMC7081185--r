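---
title: "Dual-contrast vessel size imaging: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-contrast vessel size imaging: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement model

A blood-pool susceptibility contrast agent (superparamagnetic iron oxide,
SPION) raises the magnetic susceptibility of blood relative to tissue by
$\Delta\chi$. Vessels then perturb the local magnetic field, and water
protons diffusing through these perturbations lose phase coherence. The
change in transverse relaxation rate measured with a gradient echo,
$\Delta R_2^*$, is driven by the total field inhomogeneity and is largely
independent of vessel caliber; the spin-echo change $\Delta R_2$ is
refocusing-limited and peaks for capillary-scale vessels. Their ratio
therefore encodes vessel size, and suitable combinations encode vessel
density:

$$\mathrm{VSI}\,(\mu m) = 0.424\,\bigl(D/(\gamma\Delta\chi B_0)\bigr)^{1/2}
  \bigl(\Delta R_2^*/\Delta R_2\bigr)^{3/2},\qquad
  Q = \Delta R_2/(\Delta R_2^*)^{2/3},\qquad
  \mathrm{MVD} \approx Q^3/(4.725\,D).$$

`vsimri` implements (i) a Monte Carlo finite-perturber simulator that
predicts $\Delta R_2$ and $\Delta R_2^*$ for random-cylinder vascular
substrates, (ii) voxel-wise relaxometry and VSI/Q/MVD mapping, (iii)
maximal-inscribed-sphere vessel diameter morphometry for angiographic
volumes, and (iv) ADC-threshold ischemic-edema classification with ROI
statistics. Seeded phantom generators provide every input with known
ground truth.

# The finite-perturber simulator

## Substrate

`generate_cylinder_substrate()` adds cylinders of a fixed radius with
uniformly random position and orientation to a periodic binary grid until
the occupied fraction first reaches the target blood volume fraction
(Bvf). Each cylinder is the chord of a random line through the box,
rasterized with periodic wrap (a voxel is intravascular when its centre
lies within the radius of the axis). On desk-scale grids a single
large-radius chord can overshoot a small Bvf target, so proposals that
would exceed the $\pm 10\%$ tolerance band are rejected and, if full
chords keep overshooting, the final cylinder is truncated to a randomly
placed sub-segment sized to the remaining budget. Consequence to keep in
mind: at radius 10 µm a 128³ box holds only one or two cylinders, so
individual substrates are not self-averaging (see the static-dephasing
section).

## Field computation

Every intravascular voxel is a finite susceptibility perturber. The total
field shift is their superposition under periodic boundary conditions,
evaluated as multiplication in k-space by the dipole factor
$1/3 - k_z^2/k^2$ ($B_0$ along the grid z-axis), with the zero-frequency
term set to zero: only field *differences* drive dephasing, so the
volume-mean shift is fixed at 0. This reproduces the classical analytic
fields: interior shift $\gamma B_0\Delta\chi_{SI}(3\cos^2\theta-1)/6$ for
a cylinder at angle $\theta$ to $B_0$ (zero external field when parallel),
exterior amplitude $\tfrac12\gamma B_0\Delta\chi_{SI}(a/\rho)^2\cos 2\phi$
when perpendicular, and the $(3\cos^2\theta-1)/r^3$ dipole far field for
compact perturbers (validated in the test suite by projection on the
dipole basis; the k-space-sampled kernel shows Gibbs ringing for a
*single* voxel along the axes, which cancels for extended sources).

## Susceptibility unit conventions

The agent dose is specified as a CGS (Gaussian-unit) volume
susceptibility, $\Delta\chi = 4.5\times10^{-7}$. Gaussian-unit dipole
physics carries a $4\pi$: the SI susceptibility entering the kernel is
$4\pi\Delta\chi$. The field computation always applies this conversion —
with the raw CGS number in an SI kernel the static-dephasing ceiling at
Bvf 2 % would be $\sim$5.6 s⁻¹, an order of magnitude below the observed
spin-echo rate changes, so no other reading is physically tenable.

The characteristic frequency $\Delta\omega_c=\gamma\Delta\chi B_0$ in the
VSI equation is a different matter: the 0.424 prefactor is calibrated for
the convention in which the CGS number is plugged in verbatim
(`chi_convention = "as_given"`, $\Delta\omega_c \approx 842.6$ rad/s at
7 T). Under that convention the simulator's derived VSI tracks the true
cylinder radius almost 1:1 across 2–10 µm. `"si_from_cgs"` exposes the
$\times 4\pi$ alternative for sensitivity analyses.

## Proton random walk

Walkers start uniformly in the extravascular space (vessels are
impermeable; a step landing inside a vessel is rejected and the walker
stays put for that step — in a continuum control experiment rejection and
specular reflection gave indistinguishable $\Delta R_2$). Each step moves
a fixed distance $\sqrt{6D\Delta t}$ — the rms three-dimensional diffusive
displacement, so the realized per-axis diffusivity equals $D$ — in a
uniformly random direction; a lattice mode (random axis-aligned steps of
the same length) is available for comparison. Note that the 1-D diffusion
length $\sqrt{2D\Delta t}$ is *not* a valid 3-D step length: it realizes
per-axis diffusivity $D/3$ and suppresses spin-echo dephasing by roughly
$(1/3)^{1/3}$, which is incompatible with the $\sim$20 s⁻¹ spin-echo rate
changes this protocol produces at Bvf 2 %, small radii (an independent
continuum Monte Carlo with the analytic cylinder field gives
$\approx 18$ s⁻¹ at true $D = 800$ µm²/s).

Phase accrues as $\Delta\omega(x)\,\Delta t$ at the occupied voxel; a spin
echo inverts the accrual sign at TE/2; $S = |\langle e^{i\phi}\rangle|$,
normalized so $S = 1$ for zero field. Rates follow as
$-\ln S(TE)/TE$. The default $\Delta t$ = 1 ms gives only 3 steps for the
3 ms gradient echo; a `substeps` factor refines the discretization
(measured effect on $\Delta R_2$ at radius 3 µm: $<5\%$), with 1 as the
protocol-faithful default.

## Problem sizes

The full-scale configuration (400³ voxels, one walker per voxel =
64,000,000, ten repetitions) is supported but not exercised by the tests.
The reduced profile used throughout — 128³ at 1 µm, $2\times10^5$
walkers, 3 repetitions — keeps radii 2–10 µm at 2–10 voxels and runs a
full radius × Bvf sweep in minutes on one CPU; Monte Carlo SDs are
reported per condition. The Fig.-3-style trend checks use 192³ so that
large-radius conditions hold several cylinders per substrate.

## The static-dephasing oracle

For $D \to 0$ the gradient-echo rate of a dilute network of randomly
oriented cylinders has the closed form
$\Delta R_2^{*\prime} = \tfrac23\,\zeta\,\delta\omega_\perp$ with
$\delta\omega_\perp = \tfrac12\gamma(4\pi\Delta\chi)B_0$ (the 2/3 is
$\langle\sin^2\theta\rangle$; the finite-time transient is $-\zeta/t$).
Two design points in the corresponding check:

* **Ensemble averaging.** With one or two cylinders per box, individual
  static FIDs show coherence beats — $-\ln S/TE$ at a fixed TE can exceed
  even the all-perpendicular bound. The closed form describes the
  configuration *ensemble*, so the check averages the signal over
  repetitions before taking the rate, and evaluates at TE 6 ms where
  $\delta\omega_\perp TE \approx 32 \gg 1$ (asymptotic regime) while the
  per-substrate exponent stays below 0.5 (no destructive-interference
  dips).
* **Grid scaling.** Without diffusion there is no intrinsic length scale,
  only $r/L$ and $r/\mathrm{voxel}$; the check runs at 2 µm voxels on a
  192³ grid (384 µm box), which holds 5–12 cylinders per substrate at
  Bvf 2 %.

# Relaxometry

Per-voxel fits of $S = S_0 e^{-rx}$ (b-value or TE axis) use a vectorized
Levenberg–Marquardt: closed-form damped 2×2 normal-equation solves across
all voxels simultaneously, initialized by log-linear regression (exact in
the noiseless limit), with converged voxels dropping out of the active
set. `minpack.lm::nlsLM` serves as the independent reference in the test
suite, never as the map engine. Background voxels — maximum series
intensity below 5 % of the series' 99th-percentile intensity — are marked
invalid, as are non-converged fits; invalid voxels are excluded from all
downstream statistics.

Precision note: with the six-b-value diffusion protocol (100–1000 s/mm²)
at Rician SNR 40 the Cramér–Rao floor alone puts the per-voxel median
relative ADC error near 3–4 %; ROI means are correspondingly tighter. The
mono-exponential fit is deliberately plain least squares without Rician
floor correction, matching standard practice for these protocols; at the
highest post-contrast $R_2^*$ the late-echo noise floor biases fitted
rates slightly downward, which affects absolute VSI less than 15 % and
none of the directional statistics.

$\Delta R_2$/$\Delta R_2^*$ maps subtract pre- from post-contrast fitted
rates (`fitted_train`), or use the first echo directly (`first_echo`).
The fitted-train spin-echo map is multiplied by an empirical calibration
factor (default 4.375) that rescales the echo-train estimate onto the
first-echo scale expected by the vessel-size equations; it is recorded in
the map's provenance and treated as an opaque protocol constant — for
phantom-rendered series, whose truth rates already live on the mapping
scale, the pipeline uses 1. Negative rate changes (common in
contralateral noise) stay in the raw maps but are excluded from VSI/Q/MVD,
whose valid voxels are non-negative by construction.

# Vessel diameter morphometry

Vasculature is segmented by a caller-supplied intensity threshold (one
shared value across longitudinal volumes of a subject). Local thickness
follows the maximal-inscribed-sphere definition: the thickness at a voxel
is the diameter of the largest sphere fully inside the structure that
covers it, computed by an exact Euclidean distance transform followed by
sphere propagation. Digital convention (distance-ridge): a sphere of
radius $r$ contains voxel centres at distance $\le r$, and the inscribed
radius at a centre is its distance to the nearest background centre. This
recovers the nominal diameters of digital balls and cylinders to within
one voxel; an isolated voxel reports 2. The exhaustive oracle in the test
suite recomputes the same definition by brute force and must agree
exactly. Two properties replace the naive "thickness ≤ 2·EDT" intuition,
which is false for covering spheres:
$2\,\mathrm{EDT}(p) \le \mathrm{th}(p) \le 2\max\mathrm{EDT}$ with
equality at the distance ridge. Main-branch selection is caller-supplied
(a labelled mask); diameters are pooled means ± SD over branch voxels.

# Lesion analysis

ROIs (hemisphere × cortex/subcortex, plus lesion) are explicit inputs.
Tissue is classified by mean ADC against 650 µm²/s (exact equality →
normal; the defining inequalities are strict and leave the boundary
open). Cutoff proportions (VSI > 10 µm, MVD > 200 mm⁻²) use strict
inequalities. Student's t (pooled-variance unpaired, or paired
differences) is computed from first principles with the t distribution
function for the two-sided p; zero-variance data yield t = 0, p = 1 when
means agree and a flagged degenerate result otherwise. Two-sided tests
throughout. The longitudinal macrovascular aggregation takes, per animal
and vessel, the maximum venous / minimum arterial diameter over early
reperfusion days and the day-7 value for the late phase.

# The brain phantom

`make_brain_phantom()` builds two half-ellipsoid hemispheres (96×96×48 at
0.3 mm by default, matching a 300 µm in-plane acquisition at desk scale)
with a cortical shell, subcortical core and a spherical subcortical
lesion. Truth values are piecewise constant: ADC 500 (lesion) vs 750
(normal) µm²/s straddling the 650 threshold; VSI 12 vs 4 µm straddling
10 µm; Q 0.6 vs 1.07 s⁻¹ᐟ³, giving MVD ≈ 57 vs 324 mm⁻² straddling
200 mm⁻² — magnitudes in the physiologic range reported for rodent
cortex and matching the direction of ischemic-edema remodeling (larger,
sparser vessels). The $\Delta R_2$/$\Delta R_2^*$ truth is back-computed
by inverting the VSI/Q relations, so the mapping stage has an exact
target and the MVD identity holds by construction. Series are rendered as
$S_0 e^{-\mathrm{rate}\,x}$ at the acquisition axes (b = 100–1000 s/mm²;
spin-echo TE 8–160 ms / 8 ms; gradient-echo TE 3–59 ms / 4 ms) with
Rician noise at SNR 40 (magnitude MRI; background is Rayleigh with mean
$\sigma\sqrt{\pi/2}$).

What the phantom does *not* emulate — and what passing tests therefore do
not establish about real data: anatomically realistic geometry, partial
volume and a distribution of vessel radii within a voxel, field
inhomogeneity beyond the contrast agent, motion, and any deviation from
mono-exponential decay. The phantom validates the *pipeline* (fitting,
mapping, classification, statistics), not the biophysical fidelity of the
VSI model in tissue; the in-vivo medians and animal-level p-values of the
source protocol depend on data that is not deposited and are out of
scope.

# Determinism

Every stochastic component takes a seed; sweep repetitions and pipeline
stages derive deterministic child seeds from the master seed, and
identical seeds give bit-identical substrates, signals, phantoms and
output manifests (file hashes are md5 over uncompressed NIfTI).
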