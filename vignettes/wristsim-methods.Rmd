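---
title: "Models and methods behind wristsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind wristsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(wristsim)
```

`wristsim` is a virtual stand-in for a muscle-activated wrist joint
motion simulator: a phantom hand driven by six motorized cables, with
load cells on every cable and optical motion capture reporting the
joint angles. This vignette documents the models, the parameters that
matter, the numerical choices, and the design decisions taken where
the problem was genuinely open — in the package's own words, so a
maintainer can judge what the passing test suite does and does not
demonstrate.

## The plant

The wrist is modelled as two decoupled rotational degrees of freedom,
flexion–extension (FE) and radioulnar deviation (RUD), with ISB sign
conventions (flexion positive, ulnar deviation positive). Each axis
obeys

$$I_j \ddot\theta_j = \sum_i r_{ij} F_i \;+\; s\, m g d \sin\theta_j
\;-\; b_j \dot\theta_j,$$

with $s = -1$ when the hand hangs below the elbow (gravity restores,
a pendulum) and $s = +1$ when it points vertically upward (an
inverted pendulum — the configuration that defeats open-loop force
control). Decoupled inertias are justified by the mechanically
decoupled FE/RUD axes of the rig being emulated; cross-coupling
inertia is deliberately omitted.

Cables can only pull. Each is a one-sided series spring,

$$F_i = \max\left(0,\; k\,(y_i - e_i(\theta))\right), \qquad
e_i(\theta) = r_{i,FE}\,\theta_{FE} + r_{i,RUD}\,\theta_{RUD},$$

where $y_i$ is the actuator position (mm, positive reels the cable
in) and $e_i$ is the tendon excursion required by the current pose.
Moment arms are constant with joint angle — the simplest model
consistent with driving tendon distribution by fixed moment-arm
ratios; angle-dependent arms are an extension point, not implemented.
Actuators are position servos with a symmetric rate limit.

### Parameters and defaults

| parameter | default | unit | rationale |
|---|---|---|---|
| `hand_mass` | 0.45 | kg | 50th-percentile male hand |
| `cog_offset` | 0.06 | m | wrist centre to hand CoG |
| `inertia_fe`, `inertia_rud` | 2e-3 | kg m² | anthropometric estimate |
| `damping_fe`, `damping_rud` | 5e-3 | N m s/rad | light rig friction; keeps the passive pendulum underdamped (ζ ≈ 0.11) so passive physics checks are informative |
| `cable_stiffness` | 2e4 | N/m | stiff steel cable with series compliance, so force control is physically meaningful |
| `actuator_max_speed` | 0.1 | m/s | linear-actuator class hardware |
| `loop_period` | 0.005 | s | control iteration time of the class of rig emulated |
| `angle_noise_sd` | 0.1 | deg | optical motion capture |
| `force_noise_sd` | 0.1 | N | in-line load cells |
| `joint_limits` | ±80 (FE), ±40 (RUD) | deg | hard stops |

The muscle table (`inst/extdata/muscles_default.csv`) carries
literature-plausible PCSAs (1.9–3.4 cm²) and signed moment arms
(4–17 mm) for FCR, FCU, ECRL, ECRB, ECU and APL, respecting the sign
structure (flexors positive about FE; FCU/ECU ulnar deviators; FCR,
ECRL, APL radial deviators; ECRB's RUD arm small and radial). Maximum
forces default to specific tension, 25 N/cm², times PCSA. These are
configuration fixtures of this package, not measured values of any
specific rig; the moment-arm matrix must have rank 2 and is validated
on load.

### What the virtual plant emulates — and what it does not

It emulates: gravity in both test orientations, cable slackening
(pull-only actuation), series cable compliance, actuator rate limits,
sensor noise, hard joint stops, and the sampling delay of a discrete
control loop. It does not emulate: carpal-level kinematics or
pronation–supination, angle-dependent moment arms and tendon
wrapping, dry friction and stiction, load-cell drift, marker-cluster
pose estimation, or structural vibration of a physical frame. Tests
passing on this plant therefore show that the control strategies are
sound against redundancy, gravity inversion, slack cables, noise and
sampling — not that any specific hardware rig would achieve the same
numbers.

## Redundant force distribution

Cascade control maps a joint-torque demand $T$ onto six nonnegative
muscle forces through the strictly convex quadratic program

$$\min \sum_{i=1}^{6} (F_i/A_i)^2 \quad \text{s.t.} \quad
\sum_i r_{ij} F_i = T_j,\;\; \sum_i F_i = \rho,\;\; F_i \ge 0,$$

where $A_i$ is the PCSA and $\rho$ (the "muscle impedance") sets the
total force and hence the co-contraction level. Because the objective
is diagonal positive definite the minimizer is unique; the package
exploits this in uniqueness and permutation-invariance tests, and
uniform PCSA scaling leaves the minimizer unchanged.

The solver is a primal active-set method on the nonnegativity bounds
with direct solves of the reduced KKT systems — written by hand
because the problem is tiny (6 variables, 3 equality rows) and runs
at every control tick, where a general-purpose QP library would be
overkill. Verification is by `oracle_enumerate()`: all $2^n$ subsets
of muscles clamped to zero, each equality-constrained subproblem
solved through its augmented KKT matrix, primal-feasible candidates
filtered, minimum objective returned. The two routes agree to 1e-6
relative error over a thousand randomized instances in the test
suite.

**Infeasibility policy** (a declared decision; the behaviour of the
original LabVIEW-era implementations is unknown): the torque
equalities take priority. If $\rho$ is incompatible with them under
$F \ge 0$, the impedance row is dropped, the relaxed problem is
solved, and the result is returned flagged `feasible = FALSE` — the
controller keeps running, as a physical rig must. All-zero constraint
rows (e.g. a degenerate single-axis reduction) are pruned when their
right-hand side is zero and flagged impossible otherwise.
`feasibility_check()` computes the minimum total force for a demand
by vertex enumeration of the corresponding linear program, so a
requested $\rho$ can be vetted before a run.

## Control strategies

All four strategies share a discrete PID with trapezoidal
integration, an anti-windup clamp on the accumulator, and a
first-order filter (τ = 20 ms) on the derivative term to tolerate
motion-capture noise.

**Position control.** Nominal excursions $e_i(\theta_d)$ of the
desired pose are always commanded; one PID per axis converts angle
error into a corrective excursion that is applied to the ECRB and
distributed to the other tendons scaled by $r_{ij}/|r_{ECRB,j}|$.
One PID per axis (rather than a single controller) is required for
2-DOF motion. With zero error the command reduces exactly to the
nominal excursions, at which all cables ride the slack boundary —
which is why plain position control can fully unload antagonists.

**Force control.** Per-muscle PI on force error (derivative forced to
zero — differentiating a noisy load-cell signal through a stiff cable
destabilizes the loop); the PI output is an actuator *rate*,
integrated into the displacement command. Input profiles are recorded
from a position-control run (`record_force_profiles()`) and replayed
through linear interpolation.

**Hybrid control** is position control with force-bound override.
The implementation is selector (override) control, the standard
industrial scheme for constraint enforcement: a floor loop tracking
$F_0$ and a ceiling loop tracking $F_{max}$ run continuously per
muscle, and the selector $\min(\max(y_{pos}, y_{floor}),
y_{ceil})$ picks the governing command. A naive discrete mode switch
with bumpless transfer was implemented first and rejected: blocking
the position correction while a prime mover sat in force mode made
the axis integral wind up, yank the muscle back, overshoot and
re-enter — a relaxation oscillation of ~20 mode switches per muscle
per cycle. The selector never blocks an upward position correction,
so the oscillation disappears (≤ 4 switches per muscle per cycle in
steady state, asserted in the suite). Inactive loops are parked one
margin (0.3 mm ≈ 6 N at default stiffness) outside the currently
governing command, which provides both bumpless transfer and
hysteresis; parking the ceiling relative to the *selected* command —
not the position command — matters, since otherwise an idle ceiling
caps the floor override. A muscle enters its floor/ceiling loop when
the measured force crosses `F0 + hysteresis_band` /
`Fmax − hysteresis_band` (band 2 N), consistent with reducing exactly
to position control when all forces sit strictly inside the band.
With `F0 = 0`, `Fmax = ∞` and a zero band on a noise-free plant,
hybrid is bit-for-bit position control (tested).

Force loops in hybrid and cascade ride on the nominal desired-pose
excursion ($y = y_\theta + y_f$): the joint-motion-induced excursion
(up to ~12 mm/s in FE-30) is fed forward and the PI only regulates
the tension offset. Without this, a pure rate integrator cannot
follow the moving joint and bound enforcement fails by several
newtons.

**Bound-compliance tolerance.** The floor tracks $F_0$ itself, so
sampling, noise and catch transients leave the measured minimum
slightly below $F_0$ — on hardware as in simulation. The suite
asserts compliance to within the hysteresis band
($\min F \ge F_0 - 2$ N); the contrast of interest is with position
control, whose minimum force is zero (fully unloaded cables).

**Cascade control.** Per-axis torque PIDs plus the acceleration
feedforward $I_j \ddot\theta_d$ (unit gain; gravity compensation is
deliberately left to feedback, the feedforward anticipates
acceleration only), the QP above, then per-muscle PI force tracking.
Commanded forces satisfy $\sum F = \rho$ exactly at every tick by
construction, which the suite checks against 140 N.

## Gain tuning

Position-loop gains come from a Ziegler–Nichols ultimate-gain
procedure run on the virtual plant itself: proportional-only probes
of a 2° step (noise-free feedback, so tuning is deterministic), peak
detection on the response, geometric-mean decay ratio of successive
peaks, and log-bisection on the proportional gain until the ratio
reaches 1. Responses that run away by more than ten times the step —
including limit-cycle saturation at the joint stops, which
masquerades as constant amplitude — are classified unstable; this
classification is what makes the bisection converge on the true
margin. The classic table ($k_p = 0.6K_u$, $k_i = 2k_p/T_u$,
$k_d = k_p T_u/8$) is then derated by 0.5 on $k_p$ and $k_i$ (the
documented manual adjustment, trading response speed for low
overshoot); the derivative filter and integral clamp are added. The
tuner recovers the analytic ultimate gain of a triple-lag benchmark
($K_u = 8$, $T_u = 2\pi/\sqrt3$) within 5 % in the suite. Cascade
torque gains (0.08 N m/deg, $k_i$ 0.8, $k_d$ 0.002) and the muscle PI
(6 mm/s per N, $k_i$ 4) were tuned by hand on the default plant and
ship as fixtures; retune after changing the plant.

## Protocol and metrics

Motions are sinusoids with a 4 s period and 3 cycles, the first
discarded as settling (waveform and cycle count are this package's
choices). FE-30 and RUD-10 are the planar motions; the dart thrower's
motion runs 30° FE and 10° RUD in phase (extension with radial
deviation to flexion with ulnar deviation, a straight line in the
RUD–FE plane); circumduction runs 20° FE against 10° RUD in
quadrature, starting at peak flexion, with the RUD sign selecting
clockwise (flexion → ulnar → extension → radial) or anticlockwise
visiting order. The out-of-plane axis of planar motions is actively
servoed to zero.

"Mean error" is the mean absolute desired–actual deviation per axis
over the evaluated cycles (absolute rather than signed, since it is
an accuracy measure). The in-plane axis is the moved axis; for
two-axis motions both errors are reported and the larger-amplitude
axis defines the percent normalization (percent error = 100 × mean
in-plane error / amplitude). Repeatability is the sample SD of mean
in-plane errors across repeated seeded runs. Extreme angles are
per-repeat maxima averaged across repeats. Co-contraction sweeps vary
$F_0$ (hybrid) or $\rho$ (cascade) with one full motion per value and
tabulate post-settling per-muscle mean forces next to the kinematic
error.

## Numerical choices

- Symplectic (semi-implicit) Euler at a 1 ms physics substep inside
  the 5 ms control period; stable for the ~13 Hz taut-cable mode and
  dissipative with damping (energy decay is asserted numerically).
  Halving the substep reduces passive-trajectory error by ≥ 1.8×
  (first-order convergence, tested).
- Joint limits are hard stops: angle clamped, velocity zeroed into
  the stop; hitting a limit marks the run `completed = FALSE` but the
  simulation continues.
- QP tolerance 1e-9 (scaled by max(1, ρ)); active-set iteration cap
  100; moment arms converted mm → m before the constraint matrix is
  formed.
- One master seed fans out via `derive_seed(seed, tag)` to named
  substreams (`rng_stream`, isolated from R's global RNG state), so
  adding a consumer of randomness never perturbs existing draws and
  identical seeds give bit-identical runs.
- Time series are written at full double precision (`%.17g`), making
  manifest-driven reruns bit-identical.

## Problem sizes used by the suites

The acceptance evaluation runs the full 12-condition tracking grid
(3 strategies × 2 planar motions × 2 orientations) at 3 cycles ×
4 s × 200 Hz per run, plus the force-control record/replay pair,
co-contraction sweeps over $F_0 \in \{5,10,15,20\}$ N and
$\rho \in \{100,140,180\}$ N, a 1000-instance randomized QP
solver-vs-oracle comparison, and 10 s passive-physics checks. These
sizes were chosen to exercise every closed-loop behaviour of interest
while keeping the whole suite in the minutes range on a single core.

## Known limitations

- Constant moment arms; no tendon wrapping or angle dependence.
- No dry friction/stiction, so the virtual plant is more benign than
  hardware at low speeds; tracking errors here should be read as
  lower bounds on what comparable hardware achieves.
- Gravity acts per axis through the same $m g d \sin\theta_j$ lever;
  the true 3-D coupling of a deviated, flexed hand is not modelled.
- The co-contraction level must be prescribed ($F_0$, $\rho$); the
  strategies cannot predict it.
- Force-control replay inherits whatever the recording run did; it is
  a faithful reproduction of the strategy's fragility, not a tuned
  baseline.
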