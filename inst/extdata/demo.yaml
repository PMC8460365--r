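# Demo pipeline configuration: a 3-second synthetic exercise capture with
# the default tracker noise phenomenology.
seed: 20
sim:
  n_frames: 90
  frame_rate: 30
  depth_noise_sd: 0.05
  xy_noise_sd: 0.005
  dropout_prob: 0.1
  cloud_points_per_limb: 150
  cloud_radius: 0.04
est:
  lower_bound_frac: 0.8
  upper_bound_frac: 1.2
  displacement_bound: 0.25
  window: 30
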