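---
title: "A planar six-muscle arm: muscle models, predictive control, and reaching metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A planar six-muscle arm: muscle models, predictive control, and reaching metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reacharm)
```

## The model

`reacharm` simulates point-to-point reaching of a planar arm with three
hinge joints (shoulder, elbow, wrist) moving in the horizontal plane, driven
by six Hill-type muscles arranged as one agonist–antagonist pair per joint.
The package exists to study how *intrinsic muscle properties* — the
activation dynamics that low-pass excitation into active state, and the
force–length–velocity (FLV) dependence of muscle strength — interact with a
simple predictive feedback controller during reaching.

The rigid-body dynamics are

$$M(q)\,\ddot q + c(q, \dot q) - f_c(q) = T, \qquad T = R\,F\,a,$$

where $q \in \mathbb{R}^3$ are joint angles, $M$ the configuration-dependent
inertia matrix, $c$ the Coriolis/centrifugal torques, $f_c$ one-sided
joint-limit torques, $R \in \mathbb{R}^{3\times 6}$ the constant moment-arm
matrix (each muscle wraps a cylinder at its joint), $F$ the diagonal
force-capacity matrix and $a \in [0,1]^6$ the activation state. The plane is
horizontal, so gravity plays no role; passive muscle force is excluded
because muscle-length excursions in these tasks are small.

Five muscle-model variants are available through `muscle_variant()`:

| variant   | activation                  | force capacity |
|-----------|-----------------------------|----------------|
| `FMAX`    | instantaneous ($a = u$)     | constant $f_{max}$ |
| `FMAX+O1` | first-order nonlinear ODE   | constant |
| `FLV+O1`  | first-order nonlinear ODE   | $f_{max} f_l(\tilde l) f_v(\tilde v)$ |
| `FMAX+O3` | third-order cascade         | constant |
| `FLV+O3`  | third-order cascade         | $f_{max} f_l(\tilde l) f_v(\tilde v)$ |

The first-order model is the standard
$A(a,u)\dot a + a = u$ with activation/deactivation time parameters
$\alpha_{act}(0.5 + 1.5a)$ and $\alpha_{deact}/(0.5+1.5a)$; the third-order
model chains three such first-order stages with time constants
$\alpha_{1..3}$ and nonlinearity coefficients $\beta_{1..3}$, which
reproduces two features of real muscle that first-order models cannot: an
electromechanical-delay-like latency between excitation and force onset,
and a rounded twitch peak that continues to rise after excitation ends.

## Parameters and their defaults

All defaults are the published reference values for this arm. The ones a
user is most likely to touch:

* **Geometry/inertia** (`arm_params()`): link lengths 0.44/0.32/0.25/0.18 m
  and masses 3.1/1.9/1.1/0.41 kg (chest, upper arm, forearm, hand); wrapping
  radii 45/41/35 mm; feasible ranges (−20°,120°), (5°,120°), (−60°,70°);
  initial posture (20°, 80°, 20°); `dt = 2` ms.
* **Muscle** (`muscle_spec()`): isometric strengths 1500/1500/1300/1000/500/300 N;
  FL shape $b = (1.3, -1.3, 0.53)$; FV shape $d = (4, 1.8, 30.24)$;
  $v_{max} = 1.6$ lengths/s; $\alpha_{O1} = (94.5, 65)$ ms;
  $\alpha_{O3} = (18, 40, 25)$ ms; $\beta_{O3} = (0.6, 0.8, 0.7)$.
* **Control** (`control_params()`): diagonal joint-space gains $K_p$
  (N·m/rad), $K_v$ (N·m·s/rad), and the prediction time $\tau$, a
  non-negative integer number of simulation steps.
* **Task** (`reach_task()`, `make_targets()`): target distance 0.2175 m,
  planned duration $1.712\,d_0^{1/3} = 1.03$ s, simulation length 4 s,
  success tolerance 1 mm.

Every default can also be overridden from a YAML file (`read_config()`).

## Design choices where the design was open

Several quantities needed by a complete implementation are not fixed by the
published description. The choices made here, and why:

* **Link inertia.** Only masses and lengths are prescribed, so each moving
  link is a uniform thin rod (COM at mid-link, $I = mL^2/12$). Tracking
  behaviour is feedback-dominated; the rod model is the simplest consistent
  choice, but closed-loop stability margins do depend on it (see
  "Control parameters are plant-specific" below).
* **Frame and target directions.** The chest is fixed along the world $-x$
  axis with the shoulder at the origin; joint angles are relative, flexion
  positive, and absolute link angles are cumulative sums measured from
  $+x$. The four targets sit at $\pm x$ ("right"/"left") and $\pm y$
  ("forward"/"back") of the initial endpoint. Under this convention the
  forward target lies 2 mm inside the edge of the reachable workspace and
  requires a nearly straight arm — matching the described difficulty of
  forward reaches.
* **Optimal muscle lengths.** Only the statement "muscles are at optimal
  length in the initial posture" is available, so $\tilde l = 1$ there by
  construction; the metre-scale $l_0$ (which only scales $\tilde v$ and the
  $\tilde l$ excursion) defaults to the length of the link distal to each
  muscle's joint (0.32/0.25/0.18 m).
* **Joint limits.** A one-sided spring–damper (10⁴ N·m/rad, 10² N·m·s/rad,
  configurable) engages outside the feasible range, with the spring force
  ramping in smoothly over a 0.5° boundary layer (`limit_width`) so that
  the constraint force is continuous at the bound — several tasks here end
  with a joint *resting* on its limit (the forward reach parks the elbow
  at its 5° bound), where a hard on/off spring would chatter. Inside
  `step_dynamics()` the limit force is folded into the velocity update
  *implicitly* (spring at the end-of-step position, damper and tangent
  stiffness at the end-of-step velocity): the wrist's inertia is
  ~0.004 kg·m², so an explicit 10⁴ N·m/rad spring would be unstable at
  the 2-ms step, while the implicit treatment is stable and leaves the
  interior dynamics untouched. This mimics how general-purpose physics
  engines solve soft joint-range constraints.
* **Integrator.** Semi-implicit Euler at 2 ms, matching the simulation
  step of the original study; no artificial joint damping. One further
  term is integrated implicitly: the *force–velocity tangent damping* of
  active FLV muscles (`fv_tangent_damping()`). The FV curve makes muscle
  force fall steeply with shortening speed, which acts as a joint damper
  with coefficient up to several N·m·s/rad when opposing muscles
  co-contract; on the wrist that damping rate exceeds 1/dt, where an
  explicit evaluation oscillates between time steps (a pure
  discretization artefact — verified to produce a period-two,
  ±4 rad/s wrist limit cycle). Treating the velocity-derivative of muscle
  force implicitly integrates the same continuous dynamics stably, the
  standard remedy for velocity-stiff muscle models in modern physics
  engines. Constant-strength (`FMAX`) variants have no velocity
  dependence and are untouched.
* **Sign of $\tilde v$.** The FV curve must decrease for shortening, so
  $\tilde v = -\dot l / (l_0 v_{max})$ (positive when the muscle shortens).

## The predictive controller

At every step the controller (i) rolls an exact copy of the plant forward
$\tau/dt$ steps holding the previous excitation constant, (ii) compares the
predicted endpoint state against the *plan at* $t + \tau$, (iii) computes a
desired torque $T_d = K_p J^\dagger (x_d - \hat x) + K_v J^\dagger (\dot x_d
- \hat{\dot x})$ through the pseudo-inverse of the Jacobian at the predicted
configuration, and (iv) inverts the muscle model under a *no-co-excitation*
rule: only the agonist of each joint's torque demand is excited,
$u = T_d / (R_{kj} F_{jj})$ clamped to $[0,1]$, the antagonist receiving
exactly zero. The force capacity $F$ used in the inversion is evaluated at
the *predicted* muscle lengths and velocities, consistent with the
controller's assumption $a(t+\tau) \approx u(t)$.

Two conventions the published description leaves open are fixed as follows
(both documented here because small gain-optimum shifts can result): the
desired trajectory is sampled at $t+\tau$ (the controller compares
prediction against plan at the predicted time), and the pseudo-inverse is
damped ($J^T(JJ^T + \lambda^2 I)^{-1}$, $\lambda = 10^{-3}$) only when the
smallest singular value of $J$ drops below $10^{-2}$, which only happens
within a few millimetres of the workspace edge.

## Twitch characterization

`twitch_characteristics()` measures the activation response to a unit
excitation pulse held for one 2-ms simulation step. Three conventions
matter and are deliberate:

* **Integration step.** The default characterization step equals the 2-ms
  simulation step, i.e. the twitch is measured exactly as the muscle
  behaves *in simulation*. Evidence that this is the convention behind the
  published calibration: the first-order model's $\alpha_{act} = 94.5$ ms
  makes its first 2-ms Euler step rise to $0.002/(0.0945 \cdot 0.5) =
  0.0423$, exactly the third-order model's published peak amplitude.
* **Time-to-peak from onset.** Twitch time-to-peak follows the
  physiological convention of measuring from *force onset*, not from the
  stimulus: the third-order cascade has a ~6-ms latency during which
  activation is essentially zero (its electromechanical-delay analogue),
  and onset is defined as activation first exceeding 1% of the peak
  (linearly interpolated). With these conventions the third-order model's
  twitch measures 70 ms to peak, amplitude 0.0423 and 82 ms
  half-relaxation with the default parameters:

```{r twitch}
unlist(twitch_characteristics(muscle_variant("FMAX+O3")))
unlist(twitch_characteristics(muscle_variant("FMAX+O1")))
```

* **Refinement.** `dt` is a free parameter; under refinement the
  characteristics converge to the continuous-time limit of the cascade
  (76 ms from stimulus / 72 ms from onset, peak 0.0403), and the test
  suite checks sub-0.5% agreement between 0.1-ms and 0.05-ms steps.

## Tasks and metrics

Reaches follow a straight minimum-jerk plan: speed profile
$v(t) = \frac{1}{T_p}\left[30 s^4 - 60 s^3 + 30 s^2\right]$, $s = t/T_p$,
whose integral is exactly one. Performance is summarised by the movement
error $e_{mv}$ (time-averaged endpoint deviation from the plan over the
whole simulation) and the stabilisation error $e_{st}$ (the same average
from the moment of first success onward). *First success* is the first
sample in the stabilisation phase ($t \ge T_p$) within 1 mm of the target;
the literal deviation condition also holds at $t = 0$, where the endpoint
starts on the plan, so restricting the search to the stabilisation phase is
required for the metric to mean what its name says. If the target is never
acquired, $t_{succ} = 0$ and $e_{st} = e_{mv}$.

Co-contraction at a joint is quantified as the instantaneous *overlap*
$\min(F_{flex}a_{flex},\, F_{ext}a_{ext})$ of the opposing muscle forces —
the standard operationalisation of "force exerted simultaneously by agonist
and antagonist" — averaged over the simulation, and normalised by the
weaker muscle's isometric strength when expressed as a percentage (the
conservative choice; the pair mean is available via `normalise = "mean"`).
The instantaneous-activation variant cannot co-contract (the antagonist's
force is identically zero under no-co-excitation), which the test suite
asserts exactly.

## Control parameters are plant-specific

The published feedback gains (`reference_gains()`) were obtained by
mixed-integer optimization against the original plant, whose exact mass
distribution, joint-limit constraint solver and pseudo-inverse conventions
are not fully specified. On this package's plant (rod-inertia links,
implicit spring–damper limits), several of those gain sets sit outside the
closed-loop stability region: the task-space PD matrix
$J M^{-1} \mathrm{diag}(K_p) J^\dagger$ depends on $M$, and with the wrist's
small inertia the high-frequency wrist mode of the printed
stabilisation-criterion gains is marginal at the 2-ms step. The published
*structure* is robust here — instantaneous activation needs no prediction,
third-order activation needs tens of milliseconds — but the precise gain
values are not transferable between plants, as the original study itself
notes by reporting multiple similar optima.

The package therefore also ships `tuned_gains()`: per-variant control
parameters re-optimized for *this* plant with the package's own
mixed-integer GA (`optimize_gains()`; methodology and budgets recorded in
`scripts/tune_gains.R`), warm-started from the published values. On this
plant they reach four-target-average errors of 1.5 µm (`FMAX`), 2.7 µm
(`FLV+O1`) and 13.7 µm (`FLV+O3`) stabilisation with 12–67 µm movement
error — the same sub-0.1-mm regime reported for the original models —
and the optimized prediction times recover the published structure:
zero for instantaneous activation, a few milliseconds for first-order,
36 ms for `FLV+O3` (published band 36–46 ms).

The exception is `FMAX+O1`, the one variant combining activation lag with
*no* force–velocity damping. On this plant its stabilisation-optimized
gains reach ~30 µm stabilisation error, but every optimum found (tens of
thousands of objective evaluations across criteria, seeds and restarts)
carries a movement error of 0.7–7 mm, dominated by the transient of the
right and forward reaches. The mechanism is visible in the traces:
without the FV damping that stabilises its FLV sibling, the first-order
lag leaves tight tracking of the fast mid-reach underdamped; the arm
overshoots, the elbow can graze its 5° bound at speed, and the recovery
transient dominates the time-averaged deviation. Nearby gain
perturbations of one part in 10⁶ change these transients several-fold,
i.e. the optima are not robust basins — which is why `tuned_gains()`
stores gains at full double precision and why this variant's movement
accuracy should be read as order-of-magnitude only. On the original
study's plant this variant tracked to 0.114 mm, so the transient
behaviour of lag-without-FV control is evidently the quantity most
sensitive to the unpublished details of the plant (mass distribution,
constraint solver); the stabilisation-phase behaviour, by contrast,
replicates here for all variants.

## The optimizer

`optimize_gains()` is a mixed-integer genetic algorithm: six continuous
genes (the diagonal $K_p$, $K_v$) with simulated binary crossover and
polynomial mutation, one integer gene ($\tau$ in simulation steps) with
uniform crossover and uniform-reset mutation, binary tournament selection
and single-candidate elitism. Simulation blow-ups score a fixed 1000-mm
penalty so the search continues. Bounds default to $K_p \in [0, 10^4]$,
$K_v \in [0, 10^3]$ (an envelope ~1.3× around the published optima) and
$\tau \in \{0..50\}$ steps. The search is deterministic given its seed,
initial populations can be seeded with known candidates (used for warm
starts and restarts), and an optional memetic finishing step
(`polish = TRUE`) refines the GA's best candidate with a Nelder–Mead
search over the continuous gains at the optimized integer horizon — the
objective is noiseless, so local refinement near the GA optimum is cheap.
The default budget is population 60 for 100 generations; the shipped
`tuned_gains()` used population 32–48 for 40–80 generations per variant
plus polish, with multiple restarts for the harder variants (the original
study likewise reports that some variants required repeated optimisation
attempts).

## What the tests do and do not show

The test suite validates the dynamics against independent oracles (a
kinetic-energy Hessian for the inertia matrix, a finite-difference
Lagrangian for the Coriolis torques, energy conservation under passive
motion, finite-difference Jacobians), the activation cascade against an
adaptive ODE solver, the controller's algebraic guarantees
(no-co-excitation, exact torque inversion for the instantaneous/constant
variant, semigroup property of prediction), the metric definitions on
constructed trajectories, and the optimizer's determinism and monotone
best-so-far. Closed-loop accuracy checks run the four standard reaches at
full length. All of this exercises an idealised planar plant with noiseless
sensing and actuation: conclusions about *relative* behaviour of muscle
models transfer to richer settings, but absolute errors (micrometre-scale
tracking) reflect the absence of noise, delay and model mismatch, not a
prediction about biological reaching.

## Known limitations

* No muscle–tendon elasticity, rate coding or motor-unit recruitment; no
  sensory or neural transmission delays — the feedback loop is conceptual.
* Constant moment arms; no bi-articular muscles; no passive force.
* The joint-limit stand-in is a stiff spring–damper, not a true
  complementarity contact model; behaviour while *resting* on a limit is
  realistic, high-speed impacts are not.
* Published gain values are reproduced as data, but exact optima are
  plant-specific; only their structure (prediction-time ranges, error
  magnitudes) is expected to replicate.
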