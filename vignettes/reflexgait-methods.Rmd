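---
title: "Methods: predictive planar gait simulation with reflex-based control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predictive planar gait simulation with reflex-based control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reflexgait)
```

# Overview

`reflexgait` generates walking *de novo*: no experimental trajectories are
tracked.  A planar musculoskeletal model is driven by a reflex-based
controller whose gains, offsets, state-machine thresholds and initial state
are free parameters; a stochastic optimizer (CMA-ES) adjusts them so that
full forward rollouts score well on a small set of high-level task terms —
move economically, keep step speeds inside a window, avoid ligament injury,
keep the head steady.  Because the controller, not a reference motion,
produces the gait, the same machinery can predict how gait *adapts* when
the model is altered, e.g. by weakening or shortening the ankle
plantarflexors.

This vignette documents the model, the controller, the objective, the
optimizer, and the numerical and design choices behind them, in enough
detail to understand what a passing test suite does and does not establish.

# Musculoskeletal model

The skeleton has seven rigid bodies — a lumped trunk (pelvis + torso + head
+ arms, with the lumbar joint welded at 5° flexion), and thigh, shank and
foot per leg — connected by a 3-DOF planar joint between pelvis and ground
and 1-DOF hip, knee and ankle joints, for 9 mobile degrees of freedom.
Sign conventions (the "coordinate ledger"): flexion positive at hip and
knee, dorsiflexion positive at the ankle, anterior pelvis tilt positive,
ground plane at $y = 0$; radians internally, degrees at file boundaries.
The knee carries a configurable tibiofemoral-translation polynomial field in
the model file; the shipped default is the zero polynomial (a pure pin),
and the dynamics core rejects nonzero values rather than silently ignoring
them.

Eighteen Hill-type muscle–tendon units (MTUs) represent the nine major
sagittal muscle groups per leg: GMAX, HAMS, ILPSO, RF, VAS, BFSH, GAS, SOL,
TA.  Inertial and muscle parameters in `inst/extdata/default_model.yaml`
are literature-informed approximations for an adult of ~1.8 m and 75.16 kg
and are meant to be edited; tests reference the shipped file, not any
external source.  Fixed modeling constants: tendon strain at maximum
isometric force 4.9% (10% for the plantarflexors GAS and SOL), maximum
fiber contraction velocity 15 optimal fiber lengths per second, activation
and deactivation time constants 10 ms and 40 ms, and reduced passive-curve
scales for HAMS, VAS and RF.

**Muscle geometry.**  Each MTU's length is an affine-plus-quadratic
function of its spanned joint angles, with the constant chosen so that at
the reference pose (all angles zero) the fiber is at optimal length and
the tendon at its slack length.  Moment arms are derived analytically from
the same polynomials, so the tendon-excursion identity
$r_j = -\partial L / \partial \theta_j$ holds exactly (it is verified by
finite differences in the tests).  This replaces 3-D path geometry with
wrapping surfaces — adequate for a planar lumped-muscle model, and the
reason fiber excursions tend to be overestimated, which is also why
$v_{max}$ is set high.

**Deficits.**  Weakness scales a muscle's maximum isometric force to 25%,
12.5% or 6.25% of its unimpaired value (mild / moderate / severe);
contracture scales its optimal fiber length to 85%, 70% or 55%.  Targets
are SOL, GAS or both plantarflexors (PF), always bilaterally, giving 18
deficit cases.  Transforms always scale from stored base values, so they
are idempotent, commute, and severity chains do not compound.

# Muscle–tendon dynamics

The curve family is a smooth exponential parameterization: only the
physiologically meaningful endpoints are fixed by the framework, and the
shapes between them are explicit coefficients in the model file:

* active force–length $f_L(\tilde l) = \exp(\ln(0.05)\,|(\tilde l - 1)/w|^3)$
  with width $w = 0.45$: equals 1 at optimal length, 0.05 at
  $\tilde l = 1 \pm w$, and effectively vanishes below $\tilde l = 0.5$;
* passive force–length: zero below optimal length, exponential with shape
  $k_{pe} = 4$ reaching 1 at 60% strain, times the per-muscle passive
  scale;
* force–velocity: the Hill hyperbola (curvature $K = 0.25$) for
  shortening, with $f_V(0) = 1$ and $f_V(-v_{max}) = 0$, joined
  $C^1$-continuously to an exponential eccentric branch with plateau
  $N = 1.5$;
* tendon: zero under slack, exponential toe region normalized to reach
  exactly $F^o_m$ at the reference strain.

Fiber state uses the standard equilibrium-dynamics formulation with a rigid
force balance and zero pennation: given activation and MTU length, the
tendon force determines the required force–velocity multiplier, whose
closed-form inverse yields the fiber velocity
($d\tilde l_m/dt$).  The activation ODE
$\dot a = (u - a)/\tau$ is advanced with the exact exponential update, so
sub-stepping is irrelevant to its accuracy.  Excitations are floored at
0.01 (configurable) to keep deactivation dynamics regular.

Static fiber–tendon equilibration (used at $t = 0$) solves the isometric
balance by damped Newton with a bisection fallback on
$\tilde l_m \in [0.2, 2.2]$, tolerance $10^{-6}$ (relative to $F^o_m$),
100-iteration cap; an MTU shorter than half its tendon slack length plus
the minimum fiber length is reported as infeasible geometry.

**Energetics.**  Per-muscle metabolic rate follows the Umberger-family
model: activation + maintenance heat $(128 f_{FT} + 25) A^{0.6}$ W/kg
(scaled by the active force–length multiplier above optimal length),
shortening heat with slow/fast-twitch coefficients
$\alpha_{ST} = 100 / \bar v_{max,ST}$ (with $\bar v_{max,ST} = v_{max}/2.5$)
and $\alpha_{FT} = 153 / \bar v_{max}$ weighted by fiber-type fraction,
lengthening heat at $0.3\,\alpha_{ST}$, a 1 W/kg resting-heat floor, and
the positive mechanical work rate of the contractile element (negative
work is not credited, and the total is clamped non-negative).  Muscle mass
is $F^o_m / \sigma \cdot \rho \cdot l^o_m$ with specific tension
$\sigma = 0.25$ MPa and density $\rho = 1059.7$ kg/m³.  The whole-body
basal rate is a free constant of the framework; the default is 1.2 W/kg,
set in the model file and added in the objective, not per muscle.

# Contact, ligaments, dynamics, integration

**Contact.**  Each foot carries one heel sphere (r = 5 cm) and two toe
spheres (r = 2.5 cm).  Normal force is Hunt–Crossley:
$F_n = \tfrac{4}{3} E^* \sqrt{R}\, d^{3/2} (1 + c\,\dot d)$, floored at
zero, with plane-strain modulus $E^* = 500{,}000$ N/m², dissipation
$c = 1$ s/m.  Friction is Coulomb with the stick/slip transition smoothed
by $\tanh(v_t / v_{trans})$, $v_{trans} = 0.1$ m/s, so the force ratio
approaches $\mu_d = 0.8$ at high slip.  These are deliberately soft
contacts; they speed up integration at the price of low-frequency GRF
oscillation at very slow speeds.

**Ligaments.**  Rotational limit springs are zero strictly inside the
engagement range (hip −30° to 120°, knee 0° to 140°, ankle −40°
plantarflexion to 20° dorsiflexion) and exponentially stiffening beyond
it, continuous at the limit; scale and e-folding width are model-file
fields.

**Equations of motion.**  For the fixed 9-DOF planar topology the
joint-space mass matrix, bias forces and gravity are assembled directly
from analytic center-of-mass Jacobians per body (angles are linear in the
coordinates, so no angular-rate bias terms arise), and the 9×9 SPD system
is solved by Cholesky factorization.  Contact forces enter through point
Jacobians; muscle and ligament torques act directly on their joint
coordinates.  No general-purpose physics engine is involved, which keeps
the core compact and auditable: the tests audit energy conservation of the
passive reduction (< 0.1% drift over 5 s) and the whole-body
impulse–momentum balance of contact-rich rollouts (< 1%).

**Integration.**  A Dormand–Prince 5(4) embedded Runge–Kutta scheme with
PI-free step control integrates the coupled 54-state system (9 + 9
skeletal states, 18 activations, 18 fiber lengths).  Default tolerances
are rtol $10^{-5}$ / atol $10^{-7}$ for analysis rollouts; optimization
presets use rtol $10^{-3}$, which changes objective values by far less
than the between-candidate spread CMA-ES operates on.  The maximum step is
4 ms — strictly below the shortest reflex delay (5 ms) — so delayed
signals always interpolate *recorded* history (the method of steps for
delay differential equations).  After each accepted step activations are
clamped to $[0,1]$ and normalized fiber lengths to $[0.2, 2.2]$; this
projection is inert for physiological trajectories and merely prevents
divergence under the extreme candidates a stochastic optimizer produces.
A fall — whole-body center of mass below 0.8× its initial height — ends
the rollout and records $t_{fall}$.

**Initialization.**  Pelvis horizontal position starts at 0 m; the 7
angles and 9 velocities come from the 16 free initial-state parameters;
pelvis height is solved by bisection so the static vertical GRF equals
half body weight; muscle fiber lengths are equilibrated at activations
taken from the controller's initial excitations (computed in a first pass
at a provisional activation of 0.05).

# Reflex controller

Each leg cycles through five phases — early stance (ES), mid-stance (MS),
pre-swing (PS), swing (S), landing preparation (LP) — with transitions:
ES→MS when the foot–pelvis horizontal distance drops below a threshold;
MS→PS when the contralateral leg enters ES (no threshold); PS→S when the
foot's GRF magnitude drops below a threshold; S→LP when the foot–pelvis
distance exceeds a threshold; LP→ES when the GRF magnitude exceeds a
threshold.  The four thresholds are free parameters.  "Foot–pelvis
distance" is measured heel-sphere center to pelvis origin, signed along
+x.  The state machine updates at accepted integrator steps from
undelayed sensors; at most one transition per leg per update.

Low-level laws produce excitations from delayed sensors:
constant $u_C = K_C$; length feedback
$u_{L+} = \max(0, K_{L+}[\,l(t-t_D) - l_o])$; velocity feedback
$u_{V+} = \max(0, K_{V+} v(t-t_D))$; force feedback
$u_{F\pm} = \pm K_{F\pm} F(t-t_D)$; and pelvis-tilt PD control
$u_{PD} = K_p[\theta(t-t_D) - \theta_o] + K_v \dot\theta(t-t_D)$, used
only for the hip-spanning muscles (ILPSO, GMAX, HAMS).  All muscle-state
laws act on their own muscle except a single negative force feedback from
SOL onto TA.  Delays follow the most proximal joint the target muscle
spans — 5 ms hip, 10 ms knee, 20 ms ankle — and 40 ms for the SOL→TA
inhibition.  Sensors are normalized (fiber length in $l^o_m$, velocity in
$l^o_m/s$, tendon force in $F^o_m$) so gains are order-one and
dimensionless, the common convention in reflex-controller software.
Contributions for a muscle are summed and clamped to $[0, 1]$ —
summation-then-clamp is the simplest combination rule with the right
saturation behavior.  Delay buffers are pre-filled with the initial values
before $t = 0$.

The law-to-phase wiring is deliberately *data*, not code:
`inst/extdata/default_controller.yaml` ships a
default following the stated constraints with exactly 70 gain/offset
parameters; with the 4 thresholds and 16 initial-state values the design
vector has 90 entries, each with a name, box bounds and a CMA-ES initial
standard deviation.  The shipped parameter *values* are a pre-trained
starting guess produced by the package's own optimizer at desk scale, and
the shipped SDs play the role of per-parameter search scales.  All code
paths are topology-agnostic; `lint_controller()` (or the
`controller-lint` CLI subcommand) verifies the census and the delay rules.

# Objective

A rollout is scored by
$J = w_{cot} J_{cot} + w_{spd} J_{spd} + w_{inj} J_{inj} + w_{head} J_{head}$
with $w_{cot} = 1$ kg·m/J, $w_{spd} = 10{,}000$ s⁻¹,
$w_{inj} = 0.1$ (N·m)⁻²s⁻¹, $w_{head} = 0.25$ s³/m².

* $J_{cot}$: time integral of gross metabolic rate (muscles + basal)
  divided by mass × distance travelled (center-of-mass fore-aft
  displacement).  It is undefined for zero displacement; during
  optimization the distance is floored at 1 cm so the search stays total
  (an explicit, documented penalty mode), and an infeasible initial pose
  scores a constant $2 w_{spd}$.
* $J_{spd}$: each completed step (contralateral foot contact to contact)
  earns $v_{s,pen} = \max(0, 1\,\text{m/s} - \Psi(v_s, v_{min}, v_{max}))$
  where $\Psi$ is the linear out-of-range penalty; contributions are
  weighted by step duration and normalized by the desired horizon:
  $J_{spd} = 1 - \sum_s t_s v_{s,pen} / (t_{des} \cdot 1\,\text{m/s})$,
  clamped to $[0, 1]$.  This normalization pins three boundary behaviors:
  an immediate fall with no steps scores 1; a completed rollout whose
  in-range steps tile the horizon scores 0; and steps completed before a
  fall keep their credit — only the step in progress at the fall and
  uncovered time earn nothing.  The last point is essential and worth
  dwelling on: the alternative convention, in which a fall voids *all*
  step credit, makes every falling candidate score exactly
  $J_{spd} = 1$, a plateau on which a shooting optimizer cannot
  distinguish a 0.1 s collapse from 4 s of successful walking.  Under the
  implemented convention the speed term grades survival-with-stepping
  continuously, which is what makes the training loop work at all.
* $J_{inj} = \int \sum_j T_j^2\,dt$ over the ligament torques.
* $J_{head} = \int [\Psi(a_x)^2 + \Psi(a_y)^2]\,dt$ over the head-point
  accelerations with bounds ±0.25 g horizontally and ±0.50 g vertically
  ($g = 9.80665$ m/s²).

All integrals use trapezoidal quadrature on the output grid.  Prescribed
speed mode allows $v_s$ within ±0.05 m/s of the target; self-selected mode
sets $v_{min} = 0.75$ m/s with an unbounded maximum (an infinity
sentinel).  The objective uses *all* steps; the exclusion of the first two
steps applies to gait analysis only.

# Optimization

The shooting optimizer is a rank-1 + rank-μ CMA-ES (population λ = 16,
parents μ = 8 by default) with cumulative step-size adaptation,
log-decreasing recombination weights, per-parameter initial standard
deviations seeding a diagonal initial covariance, and box constraints by
resampling (capped, then clipping).  Seeds make runs bit-reproducible, and
the global RNG stream is saved and restored around each run.  The restart
protocol runs sets of parallel optimizations from the same seed solution,
takes each set's best to seed the next, and stops when a set improves the
previous set's best by less than 5%.

Protocol presets describe the full-scale training protocols: prescribed-speed
(10 s rollouts, 20 parallel runs, ≤3000 generations, speeds 0.50–2.00 m/s
at 0.25 m/s intervals trained middle-out), self-selected (30 s rollouts,
10 parallel runs, ≤1500 generations), the deficit seeding chain
(unimpaired → mild → moderate → severe), a 1-hour stability rollout of an
already-trained solution, and a reduced `desk` preset (5 s rollouts,
λ = 8, ≤50 generations) for desktop-scale experimentation.  Published-scale
optimizations are cluster work — tens of hours per run on a multi-core
node, times 10–20 parallel runs, times restart sets; nothing at desk
scale should be interpreted as reproducing them.

# Gait analysis

Foot contact is detected from per-foot vertical GRF crossing 1% of body
weight with a 3-sample hysteresis (both values are arguments).  Steps are
contralateral contact to contact; gait cycles are ipsilateral contact to
contact; the first two steps are excluded from all summaries.  Step speed
is center-of-mass displacement over the step duration; step length is the
fore-aft distance between successive contralateral contact points (the
deepest contact sphere at each strike); cadence is 60 / step duration;
percent stance is stance over cycle duration × 100.

Cycle-normalized channels are linearly interpolated onto 101 samples (1%
increments) and averaged across cycles.  Comparisons to a normative band:
RMSE in SD units is the root of the *mean* squared per-sample Z-score —
the mean (rather than the sum) keeps the value a per-sample magnitude in
SD units, independent of how many cycle samples are compared; NCC is the
zero-lag Pearson correlation of mean-centered trajectories; Z-score panels
flag scalar measures strictly beyond 2 SD (with a $10^{-9}$ numerical
guard so boundary values are not flagged).  Peak measures are read off the
mean cycle rather than averaging per-cycle extrema.

`normative_fixture()` generates synthetic mean ± SD bands — sinusoid
mixtures with a stance/swing phase structure and plausible spatiotemporal
scalars — as a stand-in for laboratory normative datasets, which are not
redistributed.  The fixture reproduces the *format* and rough magnitudes
of such data, not subject trajectories: passing comparisons against it
demonstrate that the metric machinery is correct, not that a simulation
matches human gait.  Real-data users should also note that published
normative hip-angle trajectories may use a different pelvis convention
(one common dataset requires an 11.6° shift); the fixture ignores
convention shifts and leaves them to the user.

# Problem sizes, tests, and limitations

The test suite runs entirely at desk scale, by design: curve and
arithmetic oracles at closed-form points; randomized property checks
(1000 equilibrium states, 100 energetics states); a 5 s passive-pendulum
energy audit at rtol $10^{-8}$; ~1 s contact-rich rollouts for the
momentum audit; a 10-D sphere benchmark for CMA-ES; and a reduced
λ = 8 / ≤50-generation / 5 s-rollout optimization from a random design
vector.  The shipped default controller values were pre-trained with the
same machinery (λ = 16, a few hundred generations in seeded sets), which
yields multi-second stepping rather than the steady minute-scale walking
the full-scale presets target.

Known limitations: planar kinematics (no hip abduction, pelvis list or
rotation, hence exaggerated swing-phase hip/knee flexion for foot
clearance); lumped single-line muscle paths with constant-coefficient
polynomials; approximate default parameters; soft contact (GRF ringing at
very slow speeds); no fatigue, history-dependent force, or spasticity; the
energetics model is a documented Umberger-family implementation, not a
validated clone of any specific published code.
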