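---
title: "Collective acoustomagnetic guiding of microparticles: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collective acoustomagnetic guiding of microparticles: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonoguide)
```

## The guiding problem

Acoustically propelled nano- and microparticles are a leading candidate for
targeted drug delivery: ultrasound supplies energy remotely and
biocompatibly, and the particles never run out of fuel.  What has been
missing is a way to steer *many* such particles to a *common* target without
tracking any of them.  `sonoguide` simulates one solution: combine

1. a **focused ultrasound beam** whose focal spot supplies propulsion only to
   the particles inside it,
2. a **homogeneous magnetic field** that always points from the focus centre
   towards the target, aligning the (ferrimagnetic) particles' propulsion
   axes with it, and
3. an **inward spiral** of the focus over the region containing the
   particles, ending in a final orbit that grazes the target.

Particles caught by the focus swim towards the target; everyone else mostly
just reorients.  Because the spiral sweeps the whole initial region, the
scheme needs no knowledge of particle positions, works for arbitrary initial
distributions, and handles particles confined to channel networks.

## Equations of motion

Each particle i is a sphere of diameter $\sigma$ at in-plane position
$\vec r_i$ with orientation angle $\varphi_i$, evolving by overdamped
Langevin dynamics:

$$\dot{\vec r}_i = \frac{1}{\gamma_t}\left(\vec F_{int,i} + \vec F_p +
\vec F_{ext}\right) + \sqrt{2 D_t}\,\vec\xi_{t,i},\qquad
\dot\varphi_i = \frac{T_{ext}}{\gamma_r} + \sqrt{2 D_r}\,\xi_{r,i},$$

with Stokes coefficients $\gamma_t = 3\pi\eta\sigma$,
$\gamma_r = \pi\eta\sigma^3$ and Einstein diffusivities
$D = k_B T_b/\gamma$.  The three forces are

* **propulsion** $\vec F_p = v_0\,\gamma_t\,I_n(\vec r, t)\,\hat u(\varphi)$
  — a prescribed focal swimming speed $v_0$ scaled by the local normalized
  beam intensity $I_n \in [0,1]$;
* **pair interaction** — the purely repulsive Weeks–Chandler–Andersen (WCA)
  potential, $V(r) = 4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6] + \epsilon$
  for $r < 2^{1/6}\sigma$, with $\epsilon = k_B T_b$;
* **wall force** $\vec F_{ext}$ — WCA repulsion from channel walls (zero in
  homogeneous runs).

The magnetic torque is $T_{ext} = \mu B \sin(\theta_B - \varphi)$ for a
particle of moment $\mu$ in a field of magnitude $B$ at angle $\theta_B$.
Magnetic dipole–dipole interactions are omitted: at an areal packing density
of $2\times10^{-8}$ they are negligible, and they would depend strongly on
details of the particle design.

### Parameters and their provenance

| quantity | default | unit | rationale |
|---|---|---|---|
| $\sigma$ | 100 | nm | passes the liver and leaky tumour vasculature, too large for renal clearance |
| $v_0$ | 1 | mm/s | attainable by shape/intensity optimization within the 720 mW/cm² diagnostic limit |
| $\mu$ | 1.394e-17 | J/T | 80 nm magnetite core: 10 emu/g × 5.2 g/cm³ × (π/6)(80 nm)³, see `magneticMomentFromCore()` |
| $B$ | 1 | mT | aligns robustly ($\kappa = \mu B/k_BT_b \approx 3.26$) yet induction-safe at sub-0.1 Hz rotation |
| $\eta$ | 1e-3 | Pa·s | blood plasma |
| $T_b$ | 310 | K | body temperature |
| $\epsilon$ | $k_B T_b$ | J | passive particles keep a typical spacing of $\sigma$ |

The dimensionless alignment strength $\kappa \approx 3.26$ gives a stationary
von Mises orientation distribution with mean resultant
$\langle\cos\rangle \approx 0.83$: an aligned, in-focus population drifts at
about $0.83\,v_0$ towards the target.

## The acoustic field

A spherical-cap transducer (radius of curvature and aperture diameter both
20 cm) driven at 1 MHz is modelled by the attenuated Rayleigh–Sommerfeld
integral: each surface patch contributes
$e^{(ik - a f_{\rm MHz}) d}/d$ times its area, where $d$ is the
patch-to-field-point distance, $k = 2\pi f/c$ with $c = 1500$ m/s, and
$a = 5\ln 10$ m⁻¹ MHz⁻¹ (1 dB cm⁻¹ MHz⁻¹) is the soft-tissue amplitude
attenuation.  The cap is discretized into near-equal-area rings with patch
size at most $\lambda/6$; patch areas sum exactly to the analytic cap area,
and all field quantities are mesh-converged at that resolution (halving the
mesh moves the focal widths by far less than 0.5%).  The overall prefactor
(medium density, cap velocity amplitude) cancels when the squared pressure
is normalized to a unit-maximum intensity $I_n$.

Uniform normal velocity over the cap (the classical O'Neil model of a
focusing radiator) is assumed.  Attenuation pulls the intensity maximum
about 0.56 mm towards the transducer, so all width measurements are taken
through the *computed* maximum, not the geometric centre of curvature.
With these choices the focal spot measures **1.521 mm (lateral) × 9.832 mm
(axial) FWHM**, an aspect ratio of 6.46 — a prolate spheroid standing along
the beam axis.  These dimensions are sensitive to the assumed sound speed
(they scale with the wavelength, about +2.7% at 1540 m/s) and to the source
motion model (a rigid-piston $\cos\theta$ obliquity weighting lowers the
aspect ratio to 6.39); the package states its model and reports what that
model gives.

For the particle dynamics the focal intensity is replaced by the spheroidal
Gaussian surrogate

$$I_n(\vec r) = \exp\!\left(-\frac{(x-x_0)^2 + (y-y_0)^2}{b_{xy}^2}
- \frac{(z-z_0)^2}{b_z^2}\right),$$

with defaults $b_{xy} = 1.790$ mm, $b_z = 11.408$ mm (aspect ratio
$\chi = 6.38$).  `fitGaussianSurrogate()` recovers such parameters from any
sampled profile by Levenberg–Marquardt; on exact Gaussian input the recovery
is better than 0.1%.  When fitted to the Rayleigh–Sommerfeld profile the
individual widths depend noticeably on the fit window, because a Gaussian
has no sidelobes to spend error on — the default window (lateral ±3 mm,
axial ±20 mm around the maximum, uniform weights, main lobe plus near
tails) gives $b_{xy} \approx 0.92$ mm, $b_z \approx 5.8$ mm, but their
*ratio* is stable at $6.30$, within 1.3% of $\chi = 6.38$.  Conclusions
should therefore rest on the ratio, not the absolute fitted widths.

## Focus trajectory and field co-rotation

The focus spirals inward at constant *tangential* speed $v_\varphi$ with
radial pitch equal to the focus diameter $2R_f$ ($R_f = 0.7927$ mm, half
the lateral FWHM of the design focus), from the rim of the initial
distribution ($R_f + R_0$, $R_0 = 1$ cm) until the focus edge touches the
target centre, then orbits once at radius $R_f$.  Closed forms follow from
$r\,\dot\varphi_f = v_\varphi$ and $dr/d\varphi = -R_f/\pi$:

$$s(t) = \frac{(R_f+R_0) - \sqrt{(R_f+R_0)^2 - 2 v_\varphi R_f t/\pi}}{R_0},
\qquad r_f = R_f + R_0(1-s), \qquad \varphi_f = \frac{\pi R_0}{R_f}\,s,$$

with spiral duration $t_1 = \pi[(R_f+R_0)^2 - R_f^2]/(2 v_\varphi R_f)$ and
orbit period $t_2 = 2\pi R_f/v_\varphi$.  Requiring $t_1 + t_2 = 600$ s
calibrates $v_\varphi = 0.391$ mm/s (`tangentialSpeedForDuration()`).  Note
$v_\varphi$ is the tangential component; the inward drift adds
$\tfrac12 (R_f/\pi r)^2$ in relative speed, under 1% except on the last two
revolutions (4.9% at $r = R_f$).

In x–z-plane runs the z-component is stretched by $(\chi - 1) R_f
\sin\varphi_f$, so the final orbit is an ellipse with semi-axes
$(R_f, \chi R_f)$ matching the spheroidal focus cross-section.  The spiral
winds counter-clockwise from start phase 0 — the physics is invariant under
this convention.  The magnetic field direction is
$-\vec r_f/\lVert\vec r_f\rVert$ (focus → target) with constant magnitude;
its angular speed stays below $2\pi \times 0.1$ rad/s for the whole plan.

## Integration presets

`simulationConfig()` bundles three presets; every field can be overridden.

* **`paper_faithful`** — $\Delta t = 0.3\ \mu$s, WCA pair interactions on,
  explicit orientation Langevin updates.  This resolves the steep WCA pair
  force ($\Delta t \ll$ interaction traversal time) and is meant for
  cluster-scale work: a full 600 s run is $2\times10^9$ steps per particle.
* **`desk_fine`** — $\Delta t = 5\ \mu$s, interactions off.  At areal
  packing density $1.96\times10^{-8}$ particle encounters are vanishingly
  rare, so dropping the pair force changes nothing measurable; the
  orientation drift per step, $(\mu B/\gamma_r)\Delta t \approx 0.022$,
  still resolves the alignment dynamics.
* **`desk_coarse`** — $\Delta t = 10$ ms, interactions off, orientation
  treated *quasi-statically*: the alignment time $\gamma_r/(\mu B) \approx
  0.23$ ms is 40× shorter than the step, so each step draws the orientation
  directly from the stationary von Mises law around the current field angle
  (Best–Fisher sampler on the run's RNG stream).  On a compressed run where
  guiding is active, `desk_fine` and `desk_coarse` agree on the target
  fraction within 0.05 at matched times.

The focus position and field angle are refreshed every 1 ms of simulated
time (configurable): the focus moves 0.4 µm per ms, four orders of magnitude
below the focal width.  All randomness flows through R's RNG from a single
seed, so every run is bit-reproducible; runs abort (and are flagged invalid)
if a particle leaves the 2.4 cm stop square, and target membership means a
particle *centre* within 1.5 mm of the origin (target diameter 3 mm).
Non-finite forces name the offending particle rather than silently
propagating NaNs.

## Channel networks

Vessel-like confinement is emulated by a union of capsules of width
$w = 500\ \mu$m along persistent random walks in a 2.4 cm square: one walk
per 1 mm of boundary (96 walks), first step perpendicular to the boundary,
each later step deviating by a Gaussian angle (sd $\pi/8$) with the
cumulative deviation from the inward normal clamped to $[-\pi/4, \pi/4]$,
stopping at the boundary.  The Gaussian-with-clamp angular law is the
package's design choice; any symmetric per-step law with a persistence
constraint of this kind yields qualitatively the same loop-free,
boundary-to-boundary channels.  A fresh network is generated per run, so
ensemble averages also average over geometries.

Walls interact with particles through the same WCA potential, realized by
chains of 100 nm wall particles spaced 50 nm apart on the capsule surface.
Because that spacing is comparable to the 112 nm WCA range, the instantaneous
chain force at a fixed gap varies by tens of percent with the lateral
registration; the package's *implicit* wall model therefore uses the
registration-averaged chain force (a continuum line integral), which is what
a particle diffusing along a wall samples, and which matches the
phase-averaged explicit summation to 0.4%.  The explicit wall-particle mode
is retained as a validation reference.  Two numerical guards apply: the WCA
divergence is capped below a gap of $\sigma/2$, and any proposed move that
would exit the capsule interior is rejected (bounce-back).  In
`desk_coarse`, where a 10 ms step moves a particle ~10 µm — two orders of
magnitude past the whole WCA range — the wall force is unresolvable and
bounce-back alone enforces confinement; this preserves confinement exactly
at the cost of sub-step wall-approach detail, which is irrelevant at the
guiding scale (µm vs mm).

Initial positions are rejection-sampled uniformly over the 2 cm disk
(intersected with the channel interior when present); initial orientations
are uniform on $[0, 2\pi)$ — the pre-alignment state of freshly injected
particles.

## Observables

`guidingSummary()` tracks the **target fraction** $\Phi(t)$ and the lower
empirical **70% distance quantile**; `radialDistribution()` bins particles
into 50 µm annuli and reports the mean packing density per annulus
(particle cross-section area over annulus area).  `ensembleStatistics()`
summarises per-run values as mean ± standard error of the mean; the sample
standard deviation is also reported for transparency.  The areal packing
density uses the square-domain convention ($l = 2$ cm), under which 1000
particles of 100 nm give $1.96\times10^{-8}$ (the disk convention would
give $2.5\times10^{-8}$).  The quantile is the lower empirical one
(sort-and-index); an interpolated convention would differ by at most one
inter-particle spacing.

## What the desk-scale runs show — and what they cannot

The simulations in the test suite run at reduced scale: 50–100 particles
instead of 1000, the `desk_coarse` integrator instead of the 0.3 µs
cluster configuration, and 10 channel runs instead of 100.  At this scale a
homogeneous x–y guiding run collects the entire ensemble within the 10 min
plan ($\Phi(600\,\mathrm{s}) \ge 0.9$, typically 1.0), guiding strictly beats
propulsion-free diffusion at every recorded time, and channel confinement
reduces the collected fraction without destroying it (ensemble mean
strictly between 0.3 and the homogeneous value).  Full-scale channel
ensembles — 100 runs of 1000 interacting particles at the 0.3 µs step,
roughly $2\times10^{12}$ particle-steps per ensemble — are cluster-scale
computations; nothing at desk scale stands in for their quantitative
collected fractions, and the package makes no claim to reproduce them.
The synthetic channel geometry is likewise a stress test, not an
anatomical model: constant diameter, no flow, no tapering, no hydrodynamic
interactions (all listed as future work for the method itself).

## Known limitations

* The acoustic model is linear, monochromatic and free-field: no nonlinear
  propagation, streaming, standing waves, or scattering off the channel
  walls.  Propulsion is prescribed ($v_0$ at focus centre), not derived
  from radiation-force physics.
* The focal dimensions depend on the assumed tissue sound speed at the
  ~3% level between 1500 and 1540 m/s; the package fixes 1500 m/s.
* Orientation quasi-statics in `desk_coarse` discards orientational
  autocorrelation below 10 ms; observables that resolve sub-alignment-time
  dynamics need `desk_fine` or `paper_faithful`.
* Two spatial dimensions per run (x–y or x–z cross-sections), as in the
  default plans; full 3-D guiding would sequence such sweeps.
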