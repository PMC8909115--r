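---
title: "Models and numerics behind tribochar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerics behind tribochar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`tribochar` estimates a composition-sensitive electrical quantity — the
contact potential difference (CPD) between a powder and a pipe wall — from
a charge measurement that takes minutes: blow a dilute powder stream
through a tube into a Faraday cup and read off the charge-to-mass ratio.
The physics connecting the two is repeated particle–wall impact charging.
This vignette describes the models, their assumptions, the tunable
parameters, and the limits of what the package's synthetic tests can show.

## The condenser model of impact charging

Each particle–wall impact is treated as a transient parallel-plate
capacitor: the contact spot of area $S$ and the wall, separated by a
critical gap $z_0$, exchange charge driven by the contact potential
difference $V_c$ (the difference in effective work functions of the two
surfaces, which depends on surface chemistry — for plant protein powders,
notably on protein content). Summed over $n$ impacts per particle, with the
initial charge negligible, the charge-to-mass ratio after transport is

$$\frac{\Delta q}{m} = \frac{6\,\varepsilon_0 V_c\, n\, k\, S}
                           {\pi D_p^3 \rho_p z_0},$$

with $\varepsilon_0 = 8.854\times10^{-12}$ F/m, particle diameter $D_p$
and density $\rho_p$, and a dimensionless charging efficiency $k$.
`charge_to_mass()` implements the forward direction, `invert_cpd()` the
algebraic inverse. The full exponential-saturation description (initial
charge, saturation level $q_{m\infty}$, characteristic collision number
$n_0$) is available in `charge_saturation()`; the linear law above is its
small-$n/n_0$ limit, and a test verifies the slope agreement numerically.

The contact area is the Hertzian maximum for an elastic sphere striking a
plane at normal speed $v_i$:

$$S = 1.36\,k_e^{2/5} \rho_p^{2/5} D_p^2 v_i^{4/5},
\qquad k_e = \frac{1 - \nu_1^2}{E_1} + \frac{1 - \nu_2^2}{E_2}.$$

**The $k/z_0$ caveat.** Neither the charging efficiency $k$ (default 1)
nor the critical gap $z_0$ (default $2.5\times10^{-7}$ m) is measurable
with this apparatus, so any absolute CPD the package reports is defined
only up to the factor $z_0/k$. Every *correlation* between CPD and
composition is invariant to this scale — a property test rescales both and
checks that Pearson and Spearman correlations with protein content are
bit-identical. Treat absolute volt values as relative indices unless $k$
and $z_0$ have been calibrated independently.

Default elastic constants are $E_1 = 2$ GPa, $\nu_1 = 0.3$ for the powder
(a stiff biopolymer particle) and $E_2 = 0.5$ GPa, $\nu_2 = 0.46$ for a
PTFE wall. CPD estimates depend on them only through
$S^{-1} \propto k_e^{-2/5}$, i.e. weakly: a factor 2 error in a modulus
moves $V_c$ by $\sim$30%, uniformly across samples, so correlations are
again unaffected.

## Gas phase: analytic fully developed pipe flow

The tracker needs only the mean axial profile and bulk fluctuation
statistics, so the gas phase is closed-form rather than a PDE solve:

* laminar ($Re < 2300$ by default): Hagen–Poiseuille,
  $u(r) = 2\bar u (1 - (r/R)^2)$, no eddies;
* turbulent: a 1/7th-power-law profile scaled so the area average equals
  $\bar u$ (default), or Reichardt's law of the wall
  (`profile = "wall_resolved"`), which resolves the viscous sublayer;
* turbulence: intensity $I = 0.16\,Re^{-1/8}$, $k = 1.5(\bar u I)^2$,
  mixing length $l = 0.07D$, $\varepsilon = C_\mu^{3/4} k^{3/2}/l$ with
  $C_\mu = 0.09$, and integral timescale $\tau_L = 0.30\,k/\varepsilon$
  (the classic eddy-lifetime constant, exposed as
  `eddy_lifetime_const`).

The reference rig (4.76 mm bore, 7 L/min $\approx$ 6.6 m/s) sits near the
laminar–turbulent transition ($Re \approx 2.1\times10^3$); the regime can
therefore be forced either way, and the characterization default forces
turbulent so dispersion is active. At $Re \approx 2.7\times10^3$ the pipe
radius is only $\sim$100 viscous units — worth keeping in mind for
everything that follows, because "near-wall" is then a quarter of the
radius.

## Lagrangian tracking and collision counting

Particles are point masses with Schiller–Naumann drag,

$$C_d = \frac{24}{Re_p}\left(1 + 0.15\,Re_p^{0.687}\right)\ (Re_p \le 10^3),
\qquad C_d = 0.44\ (Re_p > 10^3),$$

gravity transverse to the axis (horizontal pipe), and one-way coupling
(dilute flow; `solids_volume_fraction()` checks the $10^{-6}$ volume
fraction criterion and warns above it). Turbulent dispersion is a discrete
random walk: per eddy, an isotropic fluctuation
$u' \sim N(0, \sqrt{2k/3})$ held for the minimum of the eddy lifetime
$\tau_e = 0.30\,k/\varepsilon$ and the eddy crossing time. Two choices
deserve explanation:

* **Wall damping of fluctuations.** The wall-normal fluctuation component
  is multiplied by the van Driest factor $1 - e^{-y^+/A^+}$, $A^+ = 26$,
  evaluated once at eddy draw time. Without it, tracer-like particles hit
  the wall at diffusion-limited rates, which contradicts the observed
  behaviour of low-Stokes particles in this rig class (they follow the
  eddies and barely reach the wall).
* **What counts as a collision.** A wall impact is logged only if the
  particle has separated from the wall by more than 5 viscous units
  (`rebound_clearance_plus`) since its previous contact. A particle in
  sustained sliding contact otherwise chatters — hundreds of micro-impacts
  at millimetre-per-second speeds that are one physical contact, not many
  collisions.

The wall bounce is specular with restitution 1 by default (elastic smooth
spheres; real powders are dissipative, so the coefficient is exposed).
Collision detection uses the finite particle radius (contact at centre
distance $R - D_p/2$), and the pre-impact normal speed is logged as $v_i$.
Lift, Brownian motion and electrostatic feedback on trajectories are
deliberately outside the force budget: drag and gravity dominate for
10–600 µm particles at these velocities.

The integrator is semi-implicit in the drag term (the velocity update
treats the drag relaxation implicitly), so it remains stable when the time
step approaches the particle response time
$\tau_p = \rho_p d_p^2 / 18\mu$. The automatic step is
$\min(\tau_p/5,\ \tau_e/2,\ t_{transit}/2000)$; a user step that fails to
resolve $\tau_p$ is shrunk with a warning. Timed-out particles (50 nominal
transit times by default) stay in the denominator of the mean collision
number, and a run where *no* particle exits raises an error carrying the
diagnostics.

Seeding: every source of randomness flows from one master seed through
deterministic derived seeds (per sweep point, per database point, per
ensemble member, per sieved fraction — the latter derived from the
fraction's diameter, so results are invariant to row order). Identical
configuration and seed reproduce collision counts bitwise.

## What the simulator does and does not reproduce

The qualitative collision phenomenology is as expected: collision counts
rise steeply with pipe length and fall with air velocity (residence time
controls exposure); low-Stokes particles ($Stk = \tau_p/\tau_L < 1$)
barely collide; counts at the reference condition are of order a few per
particle over one metre.

Quantitatively, mean collision numbers for mid-size (40–100 µm,
moderate-to-high Stokes) particles are sensitive to the near-wall
treatment in a way this model family cannot pin down. Sustained near-wall
collision cycling requires resuspension — near-wall fluctuations exceeding
the settling velocity $\tau_p g$. Settling grows as $d_p^2$, so *any*
closure in which resuspension competes with settling makes mid-size
particles harder to recycle than fine ones; published reference values for
comparable rigs (from closed-source RANS solvers whose dispersion options,
injection conditions and wall treatments are not reported) show the
opposite ordering, with mid-size counts several times larger. The package
reports its own model's numbers and flags this as a model-fidelity limit
rather than papering over it; the density trend at 100 µm is similarly
flat here rather than clearly decreasing. Anyone needing mid-size absolute
collision numbers should calibrate the dispersion constants
(`eddy_lifetime_const`, `van_driest_aplus`, restitution, injection
vertical speed) against measurements for their own rig.

## The neural surrogate

A single tracker run is cheap here, but parameter studies over the six
operating variables (particle size 10–600 µm, density 1410–7850 kg/m³,
pipe diameter 2–6 mm, length 0.25–1.5 m, air velocity 6.5–36 m/s,
injection vertical velocity 0–1.2 m/s) motivate a regression surrogate.
`build_database()` samples the six-dimensional envelope with a Latin
hypercube (197 points by default), simulates the mean collision number at
each point (100 particles), and splits 70/15/15 into 137/30/30
train/validation/test by a floor rule. Min–max normalization uses
training-split statistics only; points outside the training envelope warn
about extrapolation.

The model is an ensemble of 30 feed-forward networks (six inputs, one
hidden layer of six logistic units, linear output) with independently
seeded initializations, fitted by `nnet` with weight decay $10^{-2}$;
the ensemble prediction is the arithmetic mean of the members. Weight
decay serves as the regulariser in place of iteration-based early
stopping — with BFGS in `nnet` there is no per-iteration validation hook —
and the validation split screens members (a member whose validation RMSE
exceeds five times the member median is dropped; the ensemble proceeds if
at least 80% survive). `neuron_sweep()` repeats the classic hidden-width
study (1–10 neurons, five seeded repeats each). RMSEs are reported in
collision-number units, so the target range (roughly 0.5–50 on the default
database) gives them scale.

Two fidelity notes, both verified by tests: the ensemble beats the
train-mean baseline comfortably, but its test RMSE does *not* reach twice
the simulator's own Monte-Carlo standard error of the mean (the label
noise floor, $\approx 0.3$ collisions at 100 particles). With 137 training
points over a six-dimensional domain and a stochastic simulator, model
error dominates label noise; reaching the noise floor would need a denser
design, not a different network.

## Characterization pipeline

`characterize()` ties everything together per sieved fraction: represent
the fraction by its volume mean diameter $D_{4,3}$ as a monodisperse size
(`generate_size_distribution()` exists for full-distribution studies of
wide or bimodal fractions), predict $n$ and $v_i$ at the rig condition
with the simulator (or $n$ with the surrogate — the surrogate does not
model $v_i$, which then still comes from a reduced simulator run), compute
$S$, convert the measured charge-to-mass ratio from nC/g to C/kg
($1\ \mathrm{nC/g} = 10^{-6}\ \mathrm{C/kg}$), invert for $V_c$, and
correlate $V_c$ with protein content. Fractions with no predicted
collisions are reported as uncharacterizable rather than silently dropped.
The rig velocity defaults to the value implied by the airflow rate
(6.56 m/s at 7 L/min in a 4.76 mm bore); an override supports matching
simulation studies run at other nominal velocities such as 8.4 m/s.

A closed-loop test injects known CPDs, forward-models the charge, runs the
full pipeline and recovers the CPDs to $10^{-6}$ relative — the pipeline
is exactly self-consistent; its accuracy on real powders is bounded by the
collision-model fidelity discussed above.

## Problem sizes and determinism of the shipped checks

The test-suite simulations use 100 particles per release and three to five
seeds per reported mean (matching the study design the tool targets — 100
particles is where the mean collision number stabilizes); the surrogate
checks use the 197-point default database. The acceptance script reruns
the reference collision conditions (25 µm and 61.7 µm flour in a
1 m × 4.76 mm pipe at 8.4 m/s) over five derived seeds and reports the
means. All of these are exactly reproducible for a given master seed, up
to floating-point differences across BLAS builds in the `nnet` fits.

## Known limitations

* Absolute CPDs carry the unknown $z_0/k$ scale factor.
* Mid-size (40–100 µm) absolute collision numbers are closure-sensitive;
  see the model-fidelity section.
* Particles below about 10 µm deposit permanently in the model (gravity
  plus damped near-wall turbulence, with lift and resuspension outside
  the force budget); the studied size range starts at 10 µm.
* Humidity, particle shape and roughness, wall fouling, solid-loading
  effects and charge back-reaction on trajectories are all out of scope.
* The one-way-coupling check warns at the default feed rate
  (1 g/min in 7 L/min is a solids volume fraction near $10^{-4}$): the
  dilute assumption there rests on the feeder releasing particles a few
  at a time, not on the time-averaged ratio.
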