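---
title: "The powered compass-gait model and its measurement pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The powered compass-gait model and its measurement pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compasswalk)
```

## The model

`compasswalk` implements the simplest walking model with hip actuation: an
inverted-pendulum stance leg and a pendular swing leg, both massless with
point feet of mass $m$, a point mass $M$ at the hip, and a trunk that stays
vertical. A torsional spring of stiffness $k$ between trunk and swing leg
mimics the burst-like activity of the proximal leg muscles: it produces
flexion torque in early swing and extension torque in terminal swing. The
stance angle $\theta$ is measured from the vertical (positive clockwise,
towards the direction of travel) and the swing angle $\phi$ from the trunk
(positive counterclockwise). Everything is dimensionless in the basis
$M = 1$, leg length $l = 1$, time $\sqrt{l/g} = 1$; the mass ratio defaults
to $\beta = m/M = 0.074$, which matches the lower-limb moment of inertia
about the hip.

During single support the dynamics are a standard two-degree-of-freedom
Lagrangian system; `eom_rhs()` solves the $2\times 2$ mass-matrix system in
closed form (the determinant $\beta(1+\beta) - \beta^2\cos^2(\theta+\phi)$
is positive for $\beta > 0$, so no iterative solve is ever needed). The
small-angle form (`linearized_rhs()`) exposes the swing leg's natural
frequency $\omega = \sqrt{1 + k/\beta}$, the quantity that ties stiffness to
cadence. Single support is conservative: `state_energy()` evaluates the
kinetic and potential energies from the point-mass kinematics directly, and
the test suite checks that trajectories conserve it to below $10^{-8}$.

Ground contact satisfies $\theta - \phi = 0$. That condition is also met
mid-swing when the legs pass each other and the swing foot grazes the ground
(scuffing), which the model ignores. The package accepts a crossing as a
heel strike only when $\theta > 0$ **and** the contact function is
increasing, $\dot\theta - \dot\phi > 0$ (the foot is descending through the
ground). The second condition matters: on the physical gait branch the scuff
occurs essentially at $\theta = 0$, and numerically it can land at slightly
positive $\theta$, so a sign test on $\theta$ alone can mistake the graze
for the landing.

At heel strike the collision is instantaneous and perfectly inelastic, and
two impulses act just before it: the push-off impulse $I_{\mathrm{push}}$
directed along the trailing leg, and a vertical gravitational impulse equal
to gravity integrated over the double-support period, modelled as inversely
proportional to the pre-collision stance velocity,
$I_{\mathrm{gravity}} = \Delta t^{DS} = \mu/\dot\theta^-$ with $\mu = 0.142$
by default (the mean value estimated from treadmill data).
`collision_transition()` implements the full four-row jump map.

## Periodic gaits as symmetric orbits

The Poincaré section is taken just after the transition, where
$\phi^+ = \theta^+$ and $\dot\phi^+ = -\dot\theta^+\cos 2\theta^+$, so the
section state is $q = (\theta, \dot\theta)$. Under the optimal push-off
hypothesis — the push-off exactly compensates the collision loss, so
$\dot\theta^- = \dot\theta^+$ — the stride-to-stride map `poincare_map()`
is deterministic given $k$, and a periodic gait is a fixed point
$q^* = f(q^*, k)$.

A fixed point requires both $\theta^- = -\theta^+$ and
$\dot\theta^- = \dot\theta^+$: two conditions, yet the searches vary a
single unknown ($\theta^+$ at fixed $k$, or $k$ at a fixed target gait).
The resolution is a symmetry. The single-support dynamics are invariant
under $(\theta, \phi, t) \to (-\theta, -\phi, -t)$, and a trajectory
beginning on the section closes into a periodic gait exactly when it passes
through the symmetry set $\theta = \phi = 0$; energy conservation then
forces the velocity matching as well. The solvers therefore drive a single
smooth residual — **the swing angle $\phi$ at the first upward crossing of
$\theta = 0$** — to zero. This residual is far better behaved than the
landing-angle defect $\theta^- + \theta^+$, which suffers grazing
bifurcations (the heel-strike event appears and disappears in pairs as $k$
varies) and admits spurious roots whose landing velocity does not match.
The Poincaré-map defect is still computed for every returned gait and
reported as `residual` (typically $10^{-11}$).

`periodic_gait()` is the package's fitting function. With
`speed` + `stiffness` it runs a damped Newton iteration on $\theta^+$
(forward finite difference, step $10^{-6}$, at most 50 iterations, step
halving when the residual fails to decrease), falling back to a bracket
scan (step 0.005 in $\theta^+$) plus Brent's method when the Newton path
fails — necessary near the slow-speed existence boundary, where the
walkable interval of $\theta^+$ is only a few hundredths of a radian wide.
With `speed` + `step_length` it brackets and root-finds over $k$; on the
monotone branch of the mid-step residual this root is unique. Integration
uses `deSolve::lsodar` with the right-hand side compiled in C, relative and
absolute tolerances $10^{-10}$ and $10^{-12}$, and event location to
$10^{-10}$.

The worked-example gait $(s, v) = (0.6, 0.39)$ yields
$k^* \approx 0.1456$ — the same scale as the hip quasi-stiffness observed in
human treadmill walking at the corresponding belt speed.

## Observables and the stiffness sweeps

For a fixed point, `section_to_gait()` gives $s = -2\sin\theta^+$ and
$v = \dot\theta^+\cos\theta^+$ (both restricted to $(0,1)$), and the package
computes the margin of stability $b = s/2 - v$, the optimal push-off
impulse in closed form, the propulsive force
$F = sv/(\mu\sqrt{4-s^2})\, I_{\mathrm{push}}$, and the maximum hip flexion
torque $T = k\,\phi_{\max}$ from 2000 uniform trajectory samples with
three-point quadratic refinement of the maximum ($\phi_{\max}$ is reported
as 0 when $k = 0$, where the torque is identically zero).

`sweep_stiffness()` continues fixed points along a stiffness grid (default
0 to 0.30 in steps of 0.005, covering the experimentally observed
quasi-stiffness range) at constant speed, seeding each solve with the
previous solution. At all six nominal belt speeds
($0.50$–$1.75\,$m/s, nondimensionalized as $v/\sqrt{9.81}$ — the printed
convention, which implies a 1 m length scale) the trends are strictly
monotone at every adjacent grid pair: $T$ rises, and $F$, $b$ and $s$ fall.
At the fastest speed the low-stiffness grid points fail because the implied
step length reaches the $s < 1$ bound; failures are recorded, not hidden.

`tuning_relations()` checks the two swing-tuning statements. The
proportionality $\omega \propto 1/\tau$ holds tightly: the
origin-constrained fit of $\omega$ against step frequency has uncentered
$R^2 > 0.999$ over the six sweeps, with slope $\approx 3.9$ (the swing leg
traverses about 0.62 of its free oscillation period per step, since it
starts with backward velocity). The approximation $\tau \approx s/v$,
however, is loose in this model and the package reports it as such: $v$ is
the heel-strike CoM speed, the fastest point of the inverted-pendulum
vault, so the true step period exceeds $s/v$ — by a median of roughly 30%
over the studied range (the stance leg slows to about half its heel-strike
speed at mid-stance, with the hip spring storing additional energy). The
relation is useful qualitatively (stiffer spring, higher cadence, shorter
steps at fixed speed) but not as a 5%-accurate identity, and the acceptance
suite records this measurement honestly rather than asserting it away.

## The measurement pipeline

`analyze_trial()` reproduces the human-gait measurement chain on a
`mocap_trial` (kinematics at 200 Hz, two-plate GRF at 1000 Hz):

1. **Filtering first**: fourth-order (net), zero-lag Butterworth low-pass —
   a second-order filter run forward and backward — at 6 Hz for kinematics
   and 18 Hz for GRF. `signal::filtfilt` has no edge handling, so
   `zero_lag_lowpass()` adds odd-reflection padding; constants pass through
   unchanged.
2. **Events**: heel strike is the last sample at or below the zero floor
   before a 10 N up-crossing of the vertical GRF; toe-off the first such
   sample after a 10 N down-crossing. The 10 N hysteresis absorbs plate
   noise of a few newtons. The floor is configurable (real plates never
   read exactly 0 N); the default exact 0 suits synthetic data. A step runs
   from one heel strike to the next contralateral one, both sides pooled
   with a side column; the last 30 steps are analysed.
3. **Per-step geometry**: the step length is the heel-to-heel X distance at
   heel strike; assuming the CoM projection bisects the step, Pythagoras
   gives the reconstructed leg length $l_{\mathrm{expt}}$, hence
   $s_{\mathrm{expt}}$. Velocities are centred finite differences of the
   filtered positions (one-sided at the boundaries); the belt is removed by
   subtracting the trailing-toe velocity at heel strike. The trailing-limb
   angle and its angular velocity follow as
   $\theta^-_{\mathrm{expt}} = \sin^{-1}(s_{\mathrm{expt}}/2)$ and
   $\dot\theta^-_{\mathrm{expt}} = v_{\mathrm{expt}}\cos\theta^- -
   v_Y\sin\theta^-$.
4. **Margin of stability**: nondimensionalized by the CoM-to-leading-heel
   distance $l_{C\text{-}H}$, $b_{\mathrm{expt}} = u_{\mathrm{expt}} -
   \xi_{\mathrm{expt}}$ with $\xi = x + \dot x$. (One printed form of this
   equation chains the three quantities with equals signs; the package
   implements the difference, consistent with the model-side definition
   $b = u - \xi$.)
5. **Double-support regression**: $\dot\theta^-_{\mathrm{expt}}$ on
   $1/\Delta t^{DS}_{\mathrm{expt}}$ without intercept;
   $\Delta t^{DS}_{\mathrm{expt}}$ is the heel-strike-to-trailing-toe-off
   period divided by $\sqrt{l_{\mathrm{expt}}/g}$, the package's time unit
   (one printed nondimensionalization inverts this ratio, which would not
   be dimensionless). $R^2 = 1 - SS_{res}/SS_{tot}$ throughout, with the
   centred total sum of squares.
6. **Quasi-stiffness**: over the window from the maximum hip extension
   during pre-swing (contralateral heel strike to ipsilateral toe-off) to
   one frame before the next ipsilateral heel strike, an ordinary
   least-squares fit of the flexion-positive torque (nondimensionalized by
   $M_{\mathrm{expt}} g\, l_{\mathrm{expt}}$) on the extension-positive
   angle; $k_{\mathrm{expt}}$ is the slope magnitude.
7. **Outcomes**: $T_{\mathrm{expt}}$ and $F_{\mathrm{expt}}$ are the peak
   swing-leg flexion torque and peak anterior GRF over the step window,
   divided by $M_{\mathrm{expt}} g\, l_{\mathrm{expt}}$ and
   $M_{\mathrm{expt}} g$.

`correlation_analysis()` correlates $k_{\mathrm{expt}}$ with
$T_{\mathrm{expt}}$, $F_{\mathrm{expt}}$, $b_{\mathrm{expt}}$ and
$s_{\mathrm{expt}}$ per belt speed, choosing Pearson when both variables
pass Shapiro–Wilk normality at 0.05 and Spearman otherwise (the normality
test is the package's choice; the source analysis does not name one), plus
one pooled $k_{\mathrm{expt}}$ versus $1/\tau_{\mathrm{expt}}$ correlation.
Significance uses $\alpha' = 1 - (1-\alpha)^{1/4} \approx 0.0127$, applied
at the rounded 0.01 level as reported.

## The synthetic-trial generator

No public recording of the original cohort exists, so `generate_trial()`
builds trials from the model itself, with stored ground truth. It emulates:
treadmill walking at the six nominal belt speeds scaled by
$\sqrt{\text{leg length}}$; 200/1000 Hz sampling; per-stride double-support
overlap following $\Delta t^{DS} = \mu/\dot\theta^-$ exactly; a hip torque
channel equal to $-k_{\mathrm{true}}\phi$ over every swing (plus a smooth
stance-phase deviation outside the quasi-stiffness window, so the window
selection is actually exercised); vertical GRF double-hump stance profiles
crossing 10 N and 0 N as the event detector expects; and an anterior GRF
with braking and propulsion lobes whose propulsion peak equals the model's
$F$ for that stride.

Three design points deserve emphasis, because they decide whether the
pipeline can recover the embedded truth at all:

- **Band-limited CoM tracks.** The CoM channels interpolate the per-stride
  position and velocity constraints at heel strike with a single-harmonic
  velocity waveform at the stride frequency. Spline-style interpolants
  place harmonic energy above the 6 Hz kinematic filter and the recovered
  heel-strike velocities come out biased by several percent; the harmonic
  construction keeps the filter's pass-band error below half a percent.
- **Marker dwell after toe-off.** The zero-lag filter is non-causal, and
  its side lobes reach about 0.1 s across the contralateral heel strike
  into the fast swing of the trailing foot, biasing the toe-velocity belt
  correction. The marker therefore dwells briefly at belt velocity after
  toe-off before the swing interpolant begins.
- **Self-calibrated force onsets.** Filtering a one-sided stance pulse
  shifts the detected 0 N crossings outward by a few milliseconds. The
  generator filters a prototype pulse through the same detection chain,
  measures the onset and offset shifts, and pre-compensates its force
  supports (three fixed-point iterations), so the detected events encode
  the intended contact times to well under a millisecond.

Stride-to-stride jitter applies lognormal variation to step length
(CV 2%) and heel-strike speed (CV 1.5%; the belt constrains speed
variability more tightly than spatial variability). Measurement noise
defaults: 1 mm on markers, 0.002 rad on angles, 2 N on forces, and AR(1)
torque noise ($\rho = 0.85$ at 200 Hz, sd 0.9 times the swing-torque scale)
calibrated once so that the quasi-stiffness fit's $R^2$ lands in the
0.68–0.79 band observed in human data while the stiffness estimate stays
within 10%. `generate_cohort()` draws 11 subjects (mass
$58.8 \pm 9.1$ kg, leg length $0.96 \pm 0.05$ m) with a per-subject
stiffness offset (sd 0.03, the observed between-subject spread) around the
speed-dependent means $0.08$–$0.16$, walking at all six speeds — up to 330
step records per speed.

On noiseless trials the pipeline recovers $s$, $v$, $b$ and $\tau$ within
2%, $k_{\mathrm{expt}}$ and $\mu_{\mathrm{expt}}$ within 1%, and the
quasi-stiffness $R^2$ equals 1 to discretization error. The double-support
fit's $R^2$ on trial data is bounded near 0.9 (not 1) by millisecond event
quantization at the force-plate rate against belt-constrained stride
variability; the inverse law itself fits exact per-step records with
$R^2 = 1$ to machine precision, and the test suite asserts both facts
separately. What the generator does **not** emulate: soft-tissue artifact,
marker gaps, force-plate crosstalk, cadence matching to humans (the model
walks at about 85 steps/min at 1.25 m/s, slower than human cadence), or any
frontal-plane motion — so passing tests validate the measurement chain and
the designed couplings, not human likeness.

## Problem sizes and runtime choices

The stiffness sweeps use the full 61-point grid at all six speeds with 1200
trajectory samples per gait (about 8 s total); synthetic trials use 35
strides per side; the cohort is the complete 11 × 6 design (about half a
minute to generate and analyse). The acceptance script re-runs all of these
from scratch in about a minute.

## Known limitations

- Orbital (Floquet) stability of the map is not computed; stability is
  discussed only through the margin of stability, as in the source
  analysis.
- The fixed-point searches target the symmetric single-step gait branch;
  period-doubled or asymmetric solutions are out of scope.
- $\tau \approx s/v$ is reported as measured (median deviation ≈ 30%), not
  enforced; see above.
- The generator's stance GRF shapes are plumbing: only event timings,
  double-support durations and the propulsion-peak scaling carry ground
  truth.
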