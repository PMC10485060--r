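# compasswalk

Simulation and analysis of the powered simple (compass-gait) walking model
with a hip torque spring, and the treadmill gait-analysis pipeline used to
test its predictions against human walking.

## The scientific problem

In elderly gait, leg swing is increasingly driven by hip flexion torque while
push-off by the ankle plantar flexors declines, and with it the propulsive
force and the margin of stability. `compasswalk` implements the minimal
mechanical model that links these observations: two massless legs of length
*l* with point feet of mass *m*, a point mass *M* at the hip, a torsional hip
spring of stiffness *k* acting on the swing leg, and two impulses applied
just before heel strike — a push-off impulse *I*<sub>push</sub> along the
trailing leg and a gravitational impulse
*I*<sub>gravity</sub> = Δt<sup>DS</sup> = μ/θ̇<sup>−</sup>, gravity
integrated over the double-support period. All quantities are dimensionless
(units *M*, *l*, √(*l*/*g*)); β = *m*/*M* = 0.074 and μ = 0.142 by default.

A periodic gait is a fixed point of the stride-to-stride Poincaré map taken
just after the transition, under the optimal push-off hypothesis (the
push-off exactly compensates the collision loss, θ̇<sup>−</sup> =
θ̇<sup>+</sup>). A fixed point with step length *s* = −2 sin θ* and walking
speed *v* = θ̇* cos θ* yields the observables

- maximum hip flexion torque *T* = max(−*k*φ) = *k*φ<sub>max</sub>,
- propulsive force *F* = *I*<sub>push</sub> sin(−θ*)/Δt<sup>DS</sup>
  = *s v*/(μ√(4−*s*²)) · *I*<sub>push</sub>,
- margin of stability *b* = *s*/2 − *v* (anterior base-of-support boundary
  minus the extrapolated centre of mass at heel strike),

and the package's central result, reproduced by `sweep_stiffness()`:
at a fixed walking speed, raising *k* raises *T* and lowers *F*, *b* and *s*.

The companion pipeline measures the same quantities in (synthetic or real)
treadmill trials: zero-lag Butterworth filtering (6 Hz kinematics, 18 Hz
GRF), 10 N-hysteresis gait-event detection on the vertical GRF, per-step
geometry and margin of stability, hip quasi-stiffness *k*<sub>expt</sub>
(slope of the swing-phase torque–angle relation), the double-support
regression θ̇<sup>−</sup> = μ<sub>expt</sub>/Δt<sup>DS</sup>, and a
per-speed correlation battery with Shapiro–Wilk normality routing and a
Bonferroni-adjusted level α′ = 1 − (1−α)<sup>1/4</sup> ≈ 0.01. A
model-driven synthetic-trial generator (`generate_trial()`,
`generate_cohort()`) provides data with known ground truth.

## Worked example

```r
library(compasswalk)

## the periodic gait with step length 0.6 at speed 0.39
g <- periodic_gait(speed = 0.39, step_length = 0.6)
g
#> Periodic gait of the powered simple walking model
#>   s = 0.6000  v = 0.3900  k* = 0.14561  tau = 2.2598  (residual 2.64e-11)
#>   T = 0.0514  F = 0.2832  b = -0.0900  omega = 1.7227
```

The solver finds the unique hip stiffness *k** = 0.1456 whose fixed point is
(s, v) = (0.6, 0.39) — the same scale as the hip quasi-stiffness observed in
human walking at the corresponding belt speed (≈ 0.14 at 1.25 m/s). The
torque trace (`plot(g)`) is flexion-positive in early swing and
extension-negative in terminal swing, and the margin of stability is
negative (the extrapolated centre of mass passes the leading foot, as in
forward walking). `simulate(g, nsim = 5, perturb = c(1e-3, 0))` rolls the
map from a perturbed start; `residuals(g)` reports the fixed-point defect.

A stiffness sweep at one of the six nominal belt speeds:

```r
sw <- sweep_stiffness(nominal_speeds()[4])   # 1.25 m/s
sw
#> Stiffness sweep at v = 0.3991: 61/61 gaits converged
#>   k in [0.000, 0.300]; s 0.768 -> 0.520; T 0.0000 -> 0.0906
```

Torque rises and propulsion, stability margin and step length fall
monotonically along the sweep.

End-to-end synthetic validation:

```r
cfg <- synthetic_config(nominal_speed = 1.25, seed = 7,
                        noise = list(marker = 0, angle = 0, grf = 0,
                                     torque_frac = 0))
rec <- analyze_trial(generate_trial(cfg))
fit_double_support(rec)
#> Double-support law fit: mu_expt = 0.1419, R^2 = 0.8762 (n = 30 steps)
mean(rec$k_expt)
#> [1] 0.1399412   # generator truth: 0.14
```

A command-line interface wrapping the same functions is installed at
`inst/cli/compasswalk.R` (subcommands `fixed-point`, `sweep`, `generate`,
`analyze`; exit codes 0/1/2 for success / computational failure / usage
error).

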