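---
title: "Repairing RGB-D skeleton streams and resolving anatomical joint angles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repairing RGB-D skeleton streams and resolving anatomical joint angles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skelkit)
```

## The data model

Commodity RGB-D body trackers report, per frame, 18 named joints in the
camera frame: x to the right, y **downward**, z pointing outward from the
sensor, in meters. `skelkit` fixes the joint table as: 0 nose, 1 chest,
2/3/4 right shoulder/elbow/wrist, 5/6/7 the left arm, 8/9/10 right
hip/knee/ankle, 11/12/13 the left leg, 14/15 right/left eye, 16/17 left/
right ear. The joint graph is a tree rooted at the nose: the chest parents
both shoulder chains and both hip chains, and the eye/ear joints parent
directly to the nose, so each of the 17 non-root joints owns exactly one
*limb* — the segment to its parent. A joint the tracker could not compute is
reported as the exact coordinate triple (0,0,0); `skeleton_frame()` treats
that sentinel, and only that sentinel (no norm threshold), as membership in
the frame's missing set. In indoor captures two error modes dominate:
per-joint depth (z) variance far in excess of the smooth image-plane x,y
trajectories, and intermittent missing joints during self-occlusion,
sometimes entire frames.

## The repair algorithm

`skeleton_repair()` estimates corrected joint positions frame by frame,
using three sources of information: temporal continuity, rigid limb lengths,
and the segmented per-limb point clouds that a depth sensor provides around
the subject's body.

**Initialization.** Within the first `window` frames (default 30, i.e. one
second at 30 Hz — long enough to contain a stable standing pose, short
enough that the subject has not started moving), the fully observed frame
with the smallest standard deviation of its 18 depth coordinates is the
reference frame; ties go to the earliest frame for determinism. The capture
protocol assumes a default standing pose — arms by the side, legs together,
facing the sensor — so that all joints are visible. The 17 child-to-parent
distances computed there form the limb-distance table, assumed constant
thereafter.

**Validation.** Joints of each subsequent frame are processed in ascending
id order, the nose first, so a child is always checked against its parent's
*already corrected* position, and the "previous frame" is always the
corrected one — estimates chain. An observation is kept when all three
hold:

* it is not missing;
* it moved at most `displacement_bound` (default 0.25 m/frame; at 30 Hz
  that is 7.5 m/s, beyond voluntary limb speed, so genuine motion never
  trips it while depth spikes of half a meter do);
* its distance to the parent lies in
  `[lower_bound_frac, upper_bound_frac] x limb distance`
  (default [0.8, 1.2]; tight enough to catch depth outliers on short limbs,
  loose enough for soft-tissue and tracking jitter).

The displacement cap and the limb interval are deliberately separate,
independently configurable checks, since they catch different failures
(temporal spikes versus anatomically impossible geometry). The root has no
limb, so only the displacement check applies to it.

**Re-estimation.** A rejected or missing joint is re-estimated from its own
limb's point-cloud segment (the root uses the head/neck segment). The
candidate is the cloud point nearest to the joint's previous position among
the points whose distance to the parent lies in the same fractional limb
interval — an interval rather than exact equality, because exact equality
has measure zero on a finite point set. Equidistant candidates resolve to
the lowest point index. If the current observation exists and the candidate
is within the displacement bound of it, the repaired position is their
midpoint (averaging keeps the unperturbed x,y information of the
observation); the midpoint is likewise used whenever it lies closer to the
previous position than the candidate alone. One guarantee is enforced on
top of the averaging rule: if the midpoint would leave the limb interval
that the candidate satisfies, the candidate alone is used, so every
*repaired* joint honors the limb bound. When no cloud point qualifies (or
no cloud is available), the previous position is carried forward and the
joint is flagged `fallback` in the repair log — continuity is preserved and
the failure is visible downstream rather than silently guessed. A missing
joint with no observation is always set to the candidate alone; averaging
with a nonexistent observation is not meaningful.

Frames before the reference frame are dropped by default
(`drop_before_reference`), because the algorithm is defined as a forward
chain from the initialization; passing them through unprocessed is
available for inspection.

## Angle extraction

`joint_angles()` resolves each frame into 18 anatomical angles:
per-side shoulder and hip triples (x, y, z), revolute elbow and knee
angles, and two vertebral-column angles. All constructions are built from
three exported primitives — `project_onto_plane()`, `angle_between()` and
`lies_between()` — and a small set of named body vectors:

* pelvis = midpoint of the two hip joints;
* Left-to-Right Shoulder, Chest-to-Pelvis;
* upper-body Forward Facing = (Left-to-Right Shoulder) x (Chest-to-Pelvis);
* lower-body Forward Facing = (Right-to-Left Hip) x (Global Up), with
  Global Up the negated camera y-axis by default (`global_up` is
  configurable for tilted sensors).

**Shoulder.** With S→E the shoulder-to-elbow vector: the y-angle
(abduction/adduction) is the angle between S→E projected onto the plane
normal to Forward Facing and the lateral shoulder axis; the z-angle
(flexion/extension) is measured against the projected lateral axis in the
plane normal to Chest-to-Pelvis. The x-angle (circumduction, i.e. twist
about the upper-arm axis) is only observable from the forearm: the
elbow-to-wrist vector is projected onto the plane normal to S→E and
measured against the projected Forward-Facing direction, with a Cross-Elbow
reference vector (projected-forward x negative S→E) deciding the sign via
the betweenness test. The twist of a straight arm is geometrically
unobservable — the construction is singular there by nature, not by
implementation.

**Hip.** The same pattern on the leg chain, with the lateral hip axis and
Global Down in place of the shoulder line and Chest-to-Pelvis: the x-angle
(internal/external thigh rotation) projects knee-to-ankle onto the plane
normal to hip-to-knee and measures it against the Backwards-Facing
projection, signed by the Cross-Knee reference.

**Elbow and knee** are revolute: the unsigned angle between
elbow-to-shoulder and elbow-to-wrist (knee-to-hip and knee-to-ankle);
180° is a straight limb.

**Vertebral column.** The x-angle (axial twist) compares the shoulder and
hip lines projected onto the horizontal plane; the z-angle (bend) measures
the pelvis-to-chest vector against Global Up in the plane normal to the
projected hip line. An upright untwisted pose gives (0, 0).

**Chirality.** Every construction is written once; the left side negates
the lateral (left-to-right) vectors, which mirrors the forward reference
with it. Elbow and knee angles are consequently symmetric under mirrored
poses.

**Sign conventions.** The betweenness sign rules are applied with *closed*
cones. Consequences worth knowing: the default standing pose (limb along
the Chest-to-Pelvis/Global-Down axis) yields y = −90° on both sides, and
poses with the projected limb on the downward side of the lateral axis are
negative. Where no sign rule is forced by the geometry (shoulder z, spine
x/z) the package fixes one and documents it: spine twist is positive when
the left shoulder rotates toward Forward Facing, spine bend is positive
forward, and shoulder z follows the same betweenness pattern as y with the
forward direction as the marker. These are conventions, not measurements;
all tests and the exporter use them consistently.

**Singularities and missing joints.** Every projection and normalization
checks its operand against a 1e-8 m norm tolerance; below it the angle is
emitted as `NA` (undefined), never silently zero. The same applies when a
joint required by a construction is missing. Gimbal configurations of this
angle parametrization are: a straight elbow/knee (twist unobservable), a
limb along the forward axis (y undefined), a limb in the lateral-vertical
boundary configuration (z undefined, e.g. the vertical limb of the standing
pose), and a shoulder line parallel to global up (spine x undefined).

**Numerical choices.** Angles are degrees throughout. `angle_between()`
uses `atan2(|u x v|, u . v)`, which is exact on exactly collinear input
(0°/180°) and equivalent to the clamped-arccos form elsewhere; dot products
are never fed to `acos` unclamped. Exact trigonometry at multiples of 90°
uses `sinpi`/`cospi`.

## Forward kinematics: the generator as the extraction's inverse

`forward_kinematics()` builds an 18-joint pose from an angle set, body
dimensions (`body_dimensions()`; defaults approximate an adult, in meters)
and a pelvis position. The construction inverts the extraction
geometry exactly: in each side's orthonormalized frame (lateral axis,
down axis, their cross product), the y/z angle pair determines the limb
direction through `(cos, -sin)` relations, and the flexion/twist pair
places the distal segment in the plane basis used by the x-angle
construction. Away from the gimbal configurations, extraction of a
generated frame recovers the input angles to ~1e-13°, which is the
round-trip contract the test suite enforces at 1e-6°. Not every y/z pair is
realizable when the torso is twisted *and* bent (the oblique shoulder frame
shifts the boundary); `forward_kinematics()` validates and refuses such
pairs rather than guessing. `NA` angle entries encode the singular-pose
conventions (zero forward component for an undefined z, zero twist for a
straight limb), which is what makes the default standing pose — arms at
the side, straight limbs — expressible.

`generate_motion()` evaluates per-angle trajectories (defaults: a gentle
bilateral arm-raise exercise with slight knee bends and torso sway, chosen
to stay inside the non-singular ranges) and returns the clean sequence plus
the ground-truth angle table. `corrupt_sequence()` then applies the
emulated tracker phenomenology: independent zero-mean Gaussian noise with
depth sd 0.05 m versus 0.005 m in x,y, i.i.d. per-joint dropout to the
(0,0,0) sentinel with probability 0.1, and optional whole-frame loss
bursts. The noise magnitudes are calibration choices — plausible for
consumer depth sensors at 2–3 m range — not measured constants; the
Gaussian/Bernoulli forms are the minimal models for the observed
phenomenology. `sample_point_clouds()` draws, per limb, points uniform in a
capsule (exact cylinder-plus-caps sampling, no rejection) of radius 0.04 m
around the true segment, from the *clean* pose: the body is visible to the
depth sensor even when the tracker drops a joint.

What the generator does **not** emulate: occlusion geometry (dropout is
independent of pose), correlated or heavy-tailed depth error, soft-tissue
deformation (limb lengths are exactly rigid), imperfect cloud segmentation
(no points from furniture or other people), and multi-person scenes.
Passing the synthetic benchmarks therefore demonstrates the estimator's
correctness under its stated assumptions, not sensor-grade performance.

## Retargeting and export

`kinematic_model()` declares the avatar rig: spherical (three-channel)
shoulders, hips and the spine joint linking the upper body to the pelvis;
revolute elbows and knees exported as a fixed-axis triple whose off-axis
channels stay zero. `write_bvh()` emits a standard BVH file (channel order
Z,X,Y per joint; the root carries three position channels with the pelvis
trajectory) whose rotation channels carry the anatomical angles directly,
with the revolute channels as `180° − angle` so a straight limb is the
zero line. Channels are written with six decimals; `read_bvh()` is a
general BVH parser, and `bvh_to_angles()` inverts the channel mapping, so
write→parse→re-pose reproduces joint positions to ~1e-8 m.
`interpolate_angles()` is linear per angle — adequate between dense
tracking frames, a documented limitation for sparse keyframes with large
rotations, where per-angle linearity is not a geodesic.

## Problem sizes and verification

The test-suite benchmarks use: 1000 random non-singular poses for the
round-trip contract (tolerance 1e-6°), 10,000 random inputs for
brute-force agreement of the geometric primitives (1e-9), 20 seeded
replicates of 300-frame captures for the repair benchmark (mean 3D error
after repair must fall below the raw error in at least 19), a 100-frame
motion for the BVH round trip (1e-3 m), and a 90-frame demo for end-to-end
byte-level determinism. `scripts/acceptance.R` recomputes all of these
from scratch at a caller-supplied seed.

## Known limitations

* The repair assumes segmented per-limb clouds are available and clean;
  with no qualifying cloud point the algorithm only carries the previous
  position forward (`fallback`), so long occlusions freeze, not
  extrapolate. A model-based smoother (e.g. a Kalman filter over joint
  trajectories) is the natural next layer and is deliberately out of scope.
* Limb distances are learned once at initialization and never re-estimated.
* Hip and spine angles reference Global Up, so they are invariant under
  rotations about the vertical but not under arbitrary re-orientation of
  the sensor; elbow, knee and shoulder angles are fully rigid-invariant.
* Head orientation is not resolved (the 18-joint model has no stable distal
  head landmarks beyond eyes/ears), and wrists/ankles carry no orientation.
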