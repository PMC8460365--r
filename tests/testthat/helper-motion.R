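# Shared fixtures: random non-singular angle sets and error metrics.

ANGLE_NAMES <- names(default_pose_angles())

# Random angle set away from the gimbal configurations of the extraction
# (limb near the lateral-vertical plane boundary, straight elbow/knee,
# spine poses tilting the shoulder frame past the realizability margin).
rand_angle_set <- function() {
  a <- default_pose_angles()
  a[c("shoulder_right_y", "shoulder_left_y")] <- runif(2, -78, -22)
  a[c("shoulder_right_z", "shoulder_left_z")] <- runif(2, -60, 60)
  a[c("shoulder_right_x", "shoulder_left_x")] <- runif(2, -150, 150)
  a[c("elbow_right", "elbow_left")] <- runif(2, 40, 150)
  a[c("hip_right_y", "hip_left_y")] <- runif(2, -85, -40)
  a[c("hip_right_z", "hip_left_z")] <- runif(2, -40, 40)
  a[c("hip_right_x", "hip_left_x")] <- runif(2, -120, 120)
  a[c("knee_right", "knee_left")] <- runif(2, 40, 150)
  a["spine_x"] <- runif(1, -20, 20)
  a["spine_z"] <- runif(1, -20, 20)
  a
}

# all 18 extracted angles of a frame, as a named vector
extract_all_angles <- function(frame) {
  c(shoulder_angles(frame, "right"), shoulder_angles(frame, "left"),
    hip_angles(frame, "right"), hip_angles(frame, "left"),
    elbow_right = elbow_angle(frame, "right"),
    elbow_left = elbow_angle(frame, "left"),
    knee_right = knee_angle(frame, "right"),
    knee_left = knee_angle(frame, "left"),
    spine_angles(frame)) |>
    stats::setNames(ANGLE_NAMES)
}

# mean 3D joint position error of `frames` against the clean ground truth,
# aligned by frame_index
mean_joint_error <- function(frames, clean) {
  tot <- 0; n <- 0
  for (f in frames) {
    tru <- clean$frames[[f$frame_index + 1L]]$positions
    tot <- tot + sum(sqrt(rowSums((f$positions - tru)^2)))
    n <- n + 18L
  }
  tot / n
}

# one corrupted replicate with the emulated study conditions and its
# before/after repair errors
repair_replicate <- function(seed, n_frames = 300L) {
  mc <- motion_config(n_frames = n_frames, seed = seed,
                      depth_noise_sd = 0.05, xy_noise_sd = 0.005,
                      dropout_prob = 0.1, cloud_radius = 0.04,
                      cloud_points_per_limb = 150L)
  gt <- generate_motion(mc)
  corr <- corrupt_sequence(gt$clean, mc)
  clouds <- lapply(gt$clean$frames, sample_point_clouds, config = mc)
  fit <- skeleton_repair(corr, clouds)
  idx <- vapply(fit$sequence$frames, `[[`, 0L, "frame_index")
  list(fit = fit, gt = gt, corr = corr,
       before = mean_joint_error(corr$frames[idx + 1L], gt$clean),
       after = mean_joint_error(fit$sequence$frames, gt$clean))
}

# rigid rotation matrix from an axis (unit) and angle in degrees
rot_axis <- function(axis, deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

transform_frame <- function(frame, R = diag(3), t = c(0, 0, 0)) {
  p <- frame$positions %*% t(R)
  p <- sweep(p, 2, -t)
  skeleton_frame(p, frame$frame_index, frame$timestamp,
                 missing = frame$missing)
}
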