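# skelkit

Post-processing for 18-joint skeleton streams from commodity RGB-D body
trackers, aimed at home monitoring and telehealth applications where a
tracked person is reconstructed as a virtual human (avatar) model.

Deep-learning RGB-D trackers emit, per frame, an 18-joint stick-figure model
in camera coordinates (x right, y **down**, z away from the sensor, meters).
Two failure modes dominate in natural indoor captures: the depth (z)
coordinate of individual joints has high variance even when the image-plane
x,y trajectories are smooth, and joints vanish under self-occlusion — the
tracker reports them as the exact sentinel `(0,0,0)`. Both wreck any naive
retargeting of the stream onto an avatar. `skelkit` implements the repair
and kinematic-resolution stack between the tracker and the avatar:

1. **Point-cloud-assisted joint repair** (`skeleton_repair()`). A reference
   frame is chosen as the fully observed frame with the lowest standard
   deviation of the 18 depth coordinates within an initial window, captured
   in a default standing pose. The child-to-parent distance of every joint
   (the *limb distance*; the joint tree is rooted at the nose) is learned
   there and treated as rigid. Each subsequent frame is processed in joint-id
   order: a joint is kept when it is observed, has moved less than the
   displacement bound since the previous corrected frame, and sits within
   `[0.8, 1.2] × limb distance` of its already-corrected parent. Otherwise
   it is re-estimated from the frame's segmented per-limb point cloud: the
   candidate is the cloud point nearest to the joint's previous position
   among those a limb distance from the parent, averaged with the current
   observation when that decreases the temporal jump.
2. **Anatomical angle extraction** (`joint_angles()`). Shoulder and hip
   rotations (x = twist/circumduction, y = abduction/adduction,
   z = flexion/extension), revolute elbow and knee flexion, and vertebral
   column twist and bend are resolved by vector geometry: named body vectors
   (Left-to-Right Shoulder, Chest-to-Pelvis with the pelvis the midpoint of
   the hips, the Forward-Facing cross product, Global Up), projections onto
   planes normal to those vectors, unsigned angles via
   `atan2(|u × v|, u·v)`, and betweenness tests that fix each sign.
3. **Retargeting and export** (`kinematic_model()`, `write_bvh()`). The
   angle series maps onto a hierarchical kinematic model — spherical
   (3-channel) shoulders, hips and spine joint, revolute (fixed-axis)
   elbows and knees — and exports as a standard BVH animation; linear
   interpolation (`interpolate_angles()`) animates in-between frames and
   bridges undefined gaps.
4. **Synthetic captures** (`generate_motion()`, `corrupt_sequence()`,
   `sample_point_clouds()`). A forward-kinematic generator produces
   ground-truth motion from known angle trajectories, corrupts it with the
   tracker's noise phenomenology (large depth noise, small x,y noise,
   Bernoulli dropout, whole-frame loss bursts) and samples capsule point
   clouds around the true limbs, so every stage is testable without a
   sensor.

## Worked example

```r
library(skelkit)
cfg <- pipeline_config(system.file("extdata", "demo.yaml", package = "skelkit"))
run <- run_pipeline(cfg, "demo_out")
print(run$fit)
#> skeleton repair: 67 frames (reference frame 23)
#>   joints kept 851, repaired 311, fallback 44
print(run$angles)
#> joint-angle series: 67 frames x 18 angles (0 undefined entries)
```

The demo simulates a 90-frame (3 s at 30 Hz) bilateral exercise with depth
noise sd 0.05 m and 10% joint dropout. Frame 23 is selected as the
initialization frame; of the 18 × 67 processed joints, 851 observations pass
the displacement/limb checks, 311 are re-estimated from the capsule point
clouds and 44 fall back to their previous position (no cloud point satisfied
the limb constraint). On this run the mean 3D joint error against the known
ground truth drops from 0.298 m (raw tracker stream, dominated by dropouts
and depth outliers) to 0.042 m after repair. `demo_out/` then contains the
corrected skeleton CSV, the per-frame angle CSV, the BVH animation, the
repair log and a JSON run report.

A thin command-line front end covering the same pipeline
(`simulate`, `filter`, `angles`, `export`, `run`) ships in
`inst/scripts/skelkit`.

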