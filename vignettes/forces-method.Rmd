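---
title: "Joint-load ergonomic risk scoring: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint-load ergonomic risk scoring: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ergoforces)
```

`ergoforces` estimates the risk of work-related musculoskeletal disorders
for a worker performing a repetitive cycle, from joint-angle motion
capture plus a declared table of external hand actions. This vignette
documents the model the package implements, the assumptions behind it,
the tunable parameters, and the design decisions taken where the method
leaves room.

## The pipeline

1. **Anthropometry.** A 16-bone articulated model (pelvis, lumbar,
   thorax, head; sided arm/forearm/hand and thigh/shin/foot) is scaled
   to the worker. Segment masses are fixed percentages of body weight
   (%W), segment centres of gravity a fixed fraction of each bone's
   length (%CG), and each segment carries a diagonal inertia tensor
   tabulated for the 5th/50th/95th population percentile of each sex.
   Body weight, when not measured, is interpolated on height between the
   percentile anchors; inertia tensors are interpolated on body weight.
2. **Kinematics.** Per-frame joint rotations (degrees, right-hand rule,
   relative to the neutral standing pose) drive forward kinematics along
   the chain from the pelvis. Angular velocity and acceleration are the
   first and second central differences of the angle curves; linear
   velocities and accelerations of joints and CGs come from
   differentiating their positions.
3. **Kinetics.** A two-stage inverse dynamics solve in kilogram-force
   units. First the body is treated as a whole and the support reactions
   are estimated so that the net force (weights + inertial loads +
   external hand loads + reactions) is zero at every frame. Then forces
   and torques are propagated joint by joint from the distal ends
   (wrists, ankles) towards the pelvis: the force at a joint is the sum
   of segment weight, inertial force, external force and reaction over
   everything distal to it; the torque adds the moments of those loads
   about the joint plus inertial torques (tensor times angular
   acceleration, plus the gyroscopic term) and declared tool torques.
4. **Risk scoring.** Each frame and joint receives five factor scores —
   angle (1–2), angular acceleration (1–1.5), force (1–2), torque
   (1–2.5) and grip (1–2, wrists only). Their product minus one is the
   frame's factor value; divided by the joint's maximum attainable
   product (23 for the wrist, 14 elsewhere) it gives the per-posture
   risk percentage. The per-minute risk is the repetitiveness-weighted
   sum of factor values, scaled to one minute by the cycle time,
   normalised by the maximum factor attainable in a minute, and
   multiplied by the organisational general factors. A banding table
   converts the percentage to a continuous 0–5 level with an
   acceptable / conditional / unacceptable interpretation.
5. **Aggregation.** Several captured variants of one workstation, and
   job rotations across workstations, combine by per-joint weighted
   arithmetic means of the per-minute risks; task order is not
   modelled.

## Units and conventions

Forces are reported in kilogram-force (kgf) and torques in kg·m, the
units of every published threshold table; SI conversion uses
g = 9.81 m/s² symmetrically so reported values stay in those units.
Angles are degrees for reporting (all thresholds are in °/s and °/s²);
radians are used internally for trigonometry. The global frame is
y vertical up, x lateral, z anterior, right-handed. Per-joint Euler
composition is intrinsic x–y–z; this choice matters little downstream
because the risk score consumes per-axis angles and acceleration moduli.
Action tables are expressed in a pelvis-linked frame whose y-axis stays
vertical: the declared vectors are rotated into the global frame by the
pelvis yaw only. Action frame ranges are inclusive at both ends and
0-based.

## Tunable parameters

* **Segment lengths** (`inst/extdata/segment_lengths.csv`): the source
  tables give masses and tensors but not per-bone lengths, so the
  package ships a Drillis–Contini-style proportional-to-stature table
  (head 0.130 H, thorax 0.150 H, arm 0.188 H, …) whose fractions sum so
  that the neutral pose stands at exactly the worker's height. The file
  is editable if a site measures its own proportions.
* **Shoulder width**: set from the measured elbow span by a linear
  factor (default 0.85, `shoulder_factor` in `build_human_model()`); the
  exact mapping is not prescribed, so it is a configurable constant.
  It has no effect on the sagittal-plane loads that dominate the
  thresholds.
* **Angle graphs** (`inst/extdata/angle_graphs.csv`,
  `shoulder_angle_grid.csv`): the per-joint posture-score breakpoints
  are editable defaults inspired by REBA/RULA/ISO 11226 band edges (for
  example lumbar flexion: neutral to 20° scores 1, rising linearly to 2
  at 60°; extension reaches 2 at −20°). Scores are always interpolated,
  never stepped, and the shoulder uses a two-input grid over elevation
  and antero-posterior rotation. Sites with calibrated graphs can drop
  their values into these files verbatim.
* **Effort thresholds** (`force_thresholds.csv`,
  `torque_thresholds.csv`): per joint and sex, the 50th-percentile
  minimum (static standing load) and maximum (99th percentile of the
  calibration captures), with coefficients transporting both to the
  P05/P95 anthropometries. For an arbitrary worker the thresholds are
  interpolated linearly on height between the three percentile anchors.
  The worker-preparation level scales the maxima by 0.9 / 1.0 / 1.1 /
  1.2.
* **Acceleration thresholds** (`acceleration_thresholds.csv`): slow and
  maximum angular speeds per joint, converted to accelerations by the
  0.2-s stop rule (acceleration = speed / 0.2).
* **Repetitiveness curve**: the weighting of high-risk frames is a
  nondecreasing piecewise-linear map from per-posture risk to a factor
  ≥ 1. Its published shape is qualitative, so the default is the
  explicit configuration (0 % → 1.0, 100 % → 2.0), linear, applied to
  the per-posture risk percentage (the curve and its abscissa are both
  arguments of `risk_per_minute()`).
* **General factors**: recovery factor 1 + 0.2 h capped at 2.6;
  micro-pauses entered directly (0.7–1); duration factor piecewise
  linear through (0 h, 0.5), (8 h, 1.1), (16 h, 2.0) — the 8 h → 1.1
  anchor is published, the end points follow the published range;
  additional factor 1 + 0.18 × proportion.
* **Support detection**: a foot is supported when its ankle is within
  5 cm of the frame's lowest foot point and moving slower than 0.3 m/s.
  The reference thresholds are not published; these defaults are
  conservative for standing work and both are arguments of
  `detect_foot_support()`. Declared seated or hand-support ranges
  override detection.

## Numerical choices and degenerate inputs

Differentiation uses central differences in the interior and one-sided
differences at the two endpoints; captures shorter than three frames are
rejected. No smoothing is applied by default (the thresholds were
derived from unsmoothed series); a Savitzky–Golay option
(`smooth_window`) is available for noisy recordings. Multi-support
indeterminacy is resolved by a lever rule: support weights minimise the
distance between the weighted support centroid and the horizontal
projection of the body CG, clamped to the simplex (for two supports this
is exactly the clamped lever rule; for more, a small active-set
enumeration). Frames with no detectable support fall back to both feet
with a warning rather than failing mid-capture. Ground contact is
modelled at the ankle point, which makes the static knee torque of an
idealized symmetric stance essentially zero. Inertia tensors are treated
as constant diagonals in the global axes, the convention in which they
are tabulated; this is an approximation, since the tabulated values do
not specify a transport rule into segment frames. Both-hands actions
split the declared vector 50/50; external hand forces act at the hand
CG and external torques enter as pure couples. Report percentages round
half-up to one decimal.

## What the synthetic generator does and does not show

`generate_synthetic_capture()` produces smooth sinusoidal-segment
trajectories for four scenarios: a neutral stand, wide calibration arcs
with an 8 kgf-per-hand declared load, a stoop lift-and-place of a 3.5 kg
part (with the matching both-hands action and hook grasp over the lift
frames), and a suspended-screwdriver task with a 0.2 kg·m tool torque.
These fixtures exercise every stage of the pipeline deterministically,
which is what the test suite needs: equilibrium, propagation, scoring
and aggregation arithmetic. They do not emulate sensor noise, soft
tissue artefact, magnetic drift, or the postural asymmetries of real
workers — so passing tests validate the computation, not the capture
hardware chain. One visible consequence: the published static *torque*
minima (e.g. lumbar 1.81 kg·m) stem from real subjects' anterior CG
offsets and sway; an idealized symmetric stance produces near-zero
static torques, and the suite therefore checks that computed static
torques do not exceed those minima while the static *force* minima are
reproduced within 0.15 kgf.

The simulated calibration protocol
(`simulate_calibration_protocol()`) runs wide arcs for each percentile
model with the 8 kgf hand loads, pools per-frame moduli, takes 99th
percentiles, averages sides and forms P05/P95 coefficients — the same
arithmetic as the published derivation, at desk scale (a few seconds of
capture at 24–30 Hz, chosen so the whole suite runs in well under a
minute). Percentile ratios from rounded published inputs occasionally
differ from the printed coefficients by one unit in the second decimal;
the derivation itself is a plain ratio with half-up rounding.

## Known limitations

* Ball-joint chain without joint limits: anatomically impossible input
  angles are processed as given.
* No muscle-level decomposition (EMG) and no ground-reaction
  measurement; reactions are estimated, not measured.
* The lever-rule support split is statically plausible but
  indeterminate in reality (two-foot stances admit many force
  distributions).
* Angle-graph defaults are literature-inspired placeholders until
  site-calibrated graphs are supplied; absolute per-workstation risks
  depend on them, while the combination/rotation arithmetic does not.
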