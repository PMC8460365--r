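#' Body segment dimensions
#'
#' Anthropometry of the synthetic subject. The primary segment lengths are
#' given directly; the 17 limb (child-to-parent) reference distances of the
#' skeleton tree are derived from them, e.g. the chest-to-hip distance is
#' `sqrt((hip_width/2)^2 + torso^2)` because the hip line is perpendicular to
#' the torso axis in the generated poses. Defaults approximate an adult in
#' meters.
#'
#' @param torso pelvis-to-chest length.
#' @param neck chest-to-nose length.
#' @param shoulder_width,hip_width full widths between the paired joints.
#' @param upper_arm,forearm,thigh,shank limb segment lengths.
#' @param eye,ear nose-to-eye and nose-to-ear distances.
#' @return Object of class `body_dims`: the parameters plus `limb_lengths`,
#'   a numeric vector named by child joint id (1-17).
#' @export
body_dimensions <- function(torso = 0.45, neck = 0.25,
                            shoulder_width = 0.36, hip_width = 0.30,
                            upper_arm = 0.28, forearm = 0.25,
                            thigh = 0.42, shank = 0.40,
                            eye = 0.07, ear = 0.11) {
  p <- c(torso = torso, neck = neck, shoulder_width = shoulder_width,
         hip_width = hip_width, upper_arm = upper_arm, forearm = forearm,
         thigh = thigh, shank = shank, eye = eye, ear = ear)
  if (any(!is.finite(p)) || any(p <= 0))
    .stopf("all body dimensions must be positive and finite")
  hipdist <- sqrt((hip_width / 2)^2 + torso^2)
  ll <- c("1" = neck,
          "2" = shoulder_width / 2, "3" = upper_arm, "4" = forearm,
          "5" = shoulder_width / 2, "6" = upper_arm, "7" = forearm,
          "8" = hipdist, "9" = thigh, "10" = shank,
          "11" = hipdist, "12" = thigh, "13" = shank,
          "14" = eye, "15" = eye, "16" = ear, "17" = ear)
  structure(c(as.list(p), list(limb_lengths = ll)), class = "body_dims")
}

#' @export
print.body_dims <- function(x, ...) {
  cat("body dimensions [m]:",
      sprintf("torso %.2f, shoulder width %.2f, hip width %.2f,",
              x$torso, x$shoulder_width, x$hip_width),
      sprintf("upper arm %.2f, forearm %.2f, thigh %.2f, shank %.2f\n",
              x$upper_arm, x$forearm, x$thigh, x$shank))
  invisible(x)
}

#' Angle set of the default standing pose
#'
#' Arms by the side, legs together, facing the sensor. Arms and legs hang
#' along the chest-to-pelvis / global-down axes, so the y-angles are -90
#' degrees and the elbow/knee angles 180; the z- and twist (x) angles are
#' gimbal-singular in this pose and therefore `NA` (unconstrained).
#'
#' @return Named numeric vector over the 18 extracted angles.
#' @export
default_pose_angles <- function() {
  a <- stats::setNames(rep(NA_real_, length(.ANGLE_NAMES)), .ANGLE_NAMES)
  a[c("shoulder_right_y", "shoulder_left_y",
      "hip_right_y", "hip_left_y")] <- -90
  a[c("elbow_right", "elbow_left", "knee_right", "knee_left")] <- 180
  a[c("spine_x", "spine_z")] <- 0
  a
}

# direction with prescribed y/z angles in the orthonormalized side frame
# (lat, down, fwd); theta_z = NA means no forward component (the z-singular
# convention used by the standing pose).
.dir_from_yz <- function(theta_y, theta_z, lat, down, fwd_unused = NULL) {
  e2 <- down
  e1 <- .vunit(lat - sum(lat * e2) * e2)
  if (is.null(e1)) .stopf("lateral axis parallel to the down axis")
  e3 <- .vunit(.vcross(e1, e2))
  if (is.na(theta_y)) {
    # arm/leg pointing along +-forward: y undefined, z = +-90 carries the sign
    if (is.na(theta_z) || abs(cospi(theta_z / 180)) > 1e-9)
      .stopf("theta_y = NA requires theta_z = +-90 (limb along the forward axis)")
    return(-sign(sinpi(theta_z / 180)) * e3)
  }
  phi <- atan2(sum(lat * e2), sum(lat * e1)) * .DEG
  chi <- phi - theta_y
  cc <- cospi(chi / 180); sc <- sinpi(chi / 180)
  if (is.na(theta_z)) {
    if (abs(cc) < 1e-9) return(sign(sc) * e2)
    v <- c(cc, sc, 0)
  } else {
    cz <- cospi(theta_z / 180); sz <- sinpi(theta_z / 180)
    if (abs(cc) < 1e-9 || abs(cz) < 1e-9)
      .stopf("angle pair (y = %.3f, z = %.3f) is gimbal-singular for this frame",
             theta_y, theta_z)
    if (sign(cc) != sign(cz))
      .stopf("angle pair (y = %.3f, z = %.3f) is not realizable: the lateral components they imply have opposite signs",
             theta_y, theta_z)
    v <- sign(cc) * c(1, sc / cc, -sz / cz)
    v <- v / .vnorm(v)
  }
  v[1L] * e1 + v[2L] * e2 + v[3L] * e3
}

# distal segment direction: flexion angle about the axis d with twist theta_x
# measured from the projected reference direction.
.distal_dir <- function(d, refdir, flex, theta_x, marker_order) {
  u <- .vunit(refdir - sum(refdir * d) * d)
  if (is.null(u))
    .stopf("limb axis parallel to the twist reference; twist undefined")
  w <- if (marker_order == "ref_first") .vcross(u, -d) else .vcross(-d, u)
  if (is.na(theta_x)) theta_x <- 0
  psi <- 180 - flex
  cospi(psi / 180) * d +
    sinpi(psi / 180) * (cospi(theta_x / 180) * u - sinpi(theta_x / 180) * w)
}

#' Forward kinematics: build a skeleton frame from joint angles
#'
#' Constructs the 18 joint positions of a pose from an anatomical angle set,
#' body dimensions and a pelvis position, using exactly the inverse of the
#' angle-extraction geometry: away from gimbal-singular configurations,
#' extracting angles from the returned frame recovers the input set. The
#' subject faces the negative camera z-axis with the hip line along camera x
#' (left hip at +x); the shoulder line and torso are posed by the spine
#' angles, arms by the shoulder/elbow angles, legs by the hip/knee angles.
#' `NA` angle entries follow the singular-pose conventions of
#' [default_pose_angles()].
#'
#' @param angle_set named numeric vector over the 18 angle names (see
#'   [default_pose_angles()] for the layout), degrees.
#' @param dims a [body_dimensions()] object.
#' @param pelvis_position 3-vector, camera frame (meters).
#' @param frame_index,timestamp metadata for the returned frame.
#' @param global_up world up direction (default negative camera y).
#' @return A `skel_frame` with no missing joints.
#' @export
forward_kinematics <- function(angle_set, dims = body_dimensions(),
                               pelvis_position = c(0, 0.3, 2.5),
                               frame_index = 0L, timestamp = 0,
                               global_up = c(0, -1, 0)) {
  a <- stats::setNames(rep(NA_real_, length(.ANGLE_NAMES)), .ANGLE_NAMES)
  a[names(angle_set)] <- angle_set
  miss <- setdiff(.ANGLE_NAMES, names(angle_set))
  if (length(miss))
    .stopf("angle_set lacks entries: %s", paste(miss, collapse = ", "))
  gup <- .vunit(global_up)
  gdown <- -gup
  # horizontal axis perpendicular to up: hip line direction (right-to-left)
  hipdir <- .vunit(.vcross(c(0, 0, 1), gup))
  if (is.null(hipdir)) hipdir <- c(1, 0, 0)
  ff_low <- .vunit(.vcross(hipdir, gup))   # lower-body forward facing

  pos <- matrix(NA_real_, 18L, 3L)
  set <- function(id, p) pos[id + 1L, ] <<- p
  pelvis <- as.numeric(pelvis_position)
  set(8L, pelvis - dims$hip_width / 2 * hipdir)   # right hip
  set(11L, pelvis + dims$hip_width / 2 * hipdir)  # left hip

  # torso from the spine angles
  sz <- a[["spine_z"]]; sx <- a[["spine_x"]]
  if (is.na(sz)) sz <- 0
  if (is.na(sx)) sx <- 0
  p2c <- cospi(sz / 180) * gup + sinpi(sz / 180) * ff_low
  chest <- pelvis + dims$torso * p2c
  set(1L, chest)
  shdir <- cospi(sx / 180) * hipdir + sinpi(sx / 180) * ff_low  # right-to-left
  set(2L, chest - dims$shoulder_width / 2 * shdir)
  set(5L, chest + dims$shoulder_width / 2 * shdir)

  # head block: nose continues the torso axis; eyes/ears at fixed offsets in
  # the torso frame, all parented to the nose
  up_h <- p2c
  nose <- chest + dims$neck * up_h
  set(0L, nose)
  lat_r <- -shdir
  fwd_up <- .vunit(.vcross(lat_r, -p2c))  # upper-body forward facing
  eye_dir <- function(lat) .vunit(0.35 * lat + 0.50 * up_h + 0.79 * fwd_up)
  ear_dir <- function(lat) .vunit(0.94 * lat + 0.33 * up_h - 0.08 * fwd_up)
  set(14L, nose + dims$eye * eye_dir(lat_r))
  set(15L, nose + dims$eye * eye_dir(-lat_r))
  set(16L, nose + dims$ear * ear_dir(-lat_r))
  set(17L, nose + dims$ear * ear_dir(lat_r))

  # arms
  down_up <- .vunit(pelvis - chest)
  for (side in c("right", "left")) {
    ids <- .arm_ids(side)
    lat <- if (side == "right") lat_r else -lat_r
    fwd <- .vunit(.vcross(lat, down_up))
    d <- .dir_from_yz(a[[paste0("shoulder_", side, "_y")]],
                      a[[paste0("shoulder_", side, "_z")]], lat, down_up)
    sh <- pos[ids[["shoulder"]] + 1L, ]
    el <- sh + dims$upper_arm * d
    set(ids[["elbow"]], el)
    ew <- .distal_dir(d, fwd, a[[paste0("elbow_", side)]],
                      a[[paste0("shoulder_", side, "_x")]], "ref_first")
    set(ids[["wrist"]], el + dims$forearm * ew)
  }

  # legs
  for (side in c("right", "left")) {
    ids <- .leg_ids(side)
    lat <- if (side == "right") -hipdir else hipdir
    fwd <- .vunit(.vcross(lat, gdown))
    t <- .dir_from_yz(a[[paste0("hip_", side, "_y")]],
                      a[[paste0("hip_", side, "_z")]], lat, gdown)
    hip <- pos[ids[["hip"]] + 1L, ]
    kn <- hip + dims$thigh * t
    set(ids[["knee"]], kn)
    ka <- .distal_dir(t, -fwd, a[[paste0("knee_", side)]],
                      a[[paste0("hip_", side, "_x")]], "d_first")
    set(ids[["ankle"]], kn + dims$shank * ka)
  }

  skeleton_frame(pos, frame_index = frame_index, timestamp = timestamp,
                 missing = rep(FALSE, 18L))
}

# ---- motion configuration and generation ----------------------------------

#' Synthetic capture configuration
#'
#' Bundles the generator's parameters: the motion itself (per-angle
#' trajectories as functions of time in seconds, or constants), the noise
#' phenomenology of RGB-D trackers (smooth x,y but high-variance depth, plus
#' intermittent joints reported as the `(0,0,0)` sentinel), and the per-limb
#' segmented point clouds. Defaults encode the emulated capture conditions:
#' depth noise sd 0.05 m against 0.005 m in x,y, 10% independent per-joint
#' dropout, and 150-point capsule clouds of radius 0.04 m per limb.
#'
#' @param n_frames number of frames.
#' @param frame_rate Hz.
#' @param angle_trajectories named list mapping angle names to `function(t)`
#'   (degrees) or single numbers; unnamed angles take the built-in neutral
#'   exercise defaults.
#' @param pelvis_trajectory `function(t)` returning the pelvis 3-position.
#' @param depth_noise_sd,xy_noise_sd zero-mean Gaussian noise sd (meters)
#'   applied per joint per frame to z and to x,y.
#' @param dropout_prob i.i.d. per-joint per-frame probability of the joint
#'   being reported as `(0,0,0)`.
#' @param burst_at,burst_len optional whole-frame loss bursts: all joints of
#'   frames `[burst_at, burst_at + burst_len)` (1-based positions) drop.
#' @param cloud_points_per_limb,cloud_radius capsule cloud density and radius.
#' @param seed integer seed making corruption and clouds reproducible.
#' @return Object of class `motion_config`.
#' @export
motion_config <- function(n_frames = 100, frame_rate = 30,
                          angle_trajectories = list(),
                          pelvis_trajectory = function(t) c(0, 0.3, 2.5),
                          depth_noise_sd = 0.05, xy_noise_sd = 0.005,
                          dropout_prob = 0.1,
                          burst_at = integer(0), burst_len = 0L,
                          cloud_points_per_limb = 150L, cloud_radius = 0.04,
                          seed = 1L) {
  if (n_frames < 1) .stopf("n_frames must be >= 1")
  if (depth_noise_sd < 0 || xy_noise_sd < 0) .stopf("noise sds must be >= 0")
  if (dropout_prob < 0 || dropout_prob > 1)
    .stopf("dropout_prob must be in [0, 1]")
  if (cloud_radius < 0) .stopf("cloud_radius must be >= 0")
  structure(list(n_frames = as.integer(n_frames), frame_rate = frame_rate,
                 angle_trajectories = angle_trajectories,
                 pelvis_trajectory = pelvis_trajectory,
                 depth_noise_sd = depth_noise_sd, xy_noise_sd = xy_noise_sd,
                 dropout_prob = dropout_prob,
                 burst_at = as.integer(burst_at),
                 burst_len = as.integer(burst_len),
                 cloud_points_per_limb = as.integer(cloud_points_per_limb),
                 cloud_radius = cloud_radius, seed = as.integer(seed)),
            class = "motion_config")
}

# neutral, everywhere-defined generation pose (all angles away from the
# gimbal configurations so ground-truth angles round-trip)
.neutral_gen_angles <- function() {
  a <- default_pose_angles()
  a[c("shoulder_right_y", "shoulder_left_y")] <- -60
  a[c("shoulder_right_z", "shoulder_left_z")] <- -10
  a[c("shoulder_right_x", "shoulder_left_x")] <- 0
  a[c("elbow_right", "elbow_left")] <- 150
  a[c("hip_right_y", "hip_left_y")] <- -80
  a[c("hip_right_z", "hip_left_z")] <- -3
  a[c("hip_right_x", "hip_left_x")] <- 0
  a[c("knee_right", "knee_left")] <- 170
  a
}

# gentle bilateral exercise used as the default motion: arm raises with
# elbow flexion, slight knee bends and torso sway, all inside the
# non-singular angle ranges
.default_trajectories <- function() {
  list(
    shoulder_right_y = function(t) -55 + 25 * sin(2 * pi * 0.25 * t),
    shoulder_left_y = function(t) -55 + 25 * sin(2 * pi * 0.25 * t + pi),
    shoulder_right_z = function(t) -15 + 10 * sin(2 * pi * 0.20 * t),
    shoulder_left_z = function(t) -15 - 10 * sin(2 * pi * 0.20 * t),
    shoulder_right_x = function(t) 15 * sin(2 * pi * 0.15 * t),
    shoulder_left_x = function(t) -15 * sin(2 * pi * 0.15 * t),
    elbow_right = function(t) 135 + 35 * sin(2 * pi * 0.30 * t),
    elbow_left = function(t) 135 - 35 * sin(2 * pi * 0.30 * t),
    hip_right_y = function(t) -78 + 6 * sin(2 * pi * 0.10 * t),
    hip_left_y = function(t) -78 - 6 * sin(2 * pi * 0.10 * t),
    hip_right_x = function(t) 8 * sin(2 * pi * 0.12 * t),
    hip_left_x = function(t) -8 * sin(2 * pi * 0.12 * t),
    knee_right = function(t) 162 + 12 * sin(2 * pi * 0.20 * t),
    knee_left = function(t) 162 - 12 * sin(2 * pi * 0.20 * t),
    spine_x = function(t) 8 * sin(2 * pi * 0.10 * t),
    spine_z = function(t) 10 + 8 * sin(2 * pi * 0.15 * t)
  )
}

#' Generate ground-truth articulated motion
#'
#' Evaluates the configured angle trajectories frame by frame and runs the
#' forward kinematics, producing a clean (fully observed) skeleton sequence
#' together with the ground-truth angle series that generated it.
#'
#' @param config a [motion_config()].
#' @param dims a [body_dimensions()].
#' @return Object of class `skel_motion`: list with `clean` (a
#'   `skel_sequence` with empty missing sets), `angles` (data frame: frame,
#'   timestamp, the 18 input angles), `dims` and `config`.
#' @export
generate_motion <- function(config = motion_config(),
                            dims = body_dimensions()) {
  traj <- .default_trajectories()
  for (nm in names(config$angle_trajectories)) {
    if (!nm %in% .ANGLE_NAMES) .stopf("unknown angle trajectory '%s'", nm)
    traj[[nm]] <- config$angle_trajectories[[nm]]
  }
  base <- .neutral_gen_angles()
  frames <- vector("list", config$n_frames)
  arows <- matrix(NA_real_, config$n_frames, length(.ANGLE_NAMES),
                  dimnames = list(NULL, .ANGLE_NAMES))
  for (i in seq_len(config$n_frames)) {
    t <- (i - 1) / config$frame_rate
    a <- base
    for (nm in names(traj)) {
      f <- traj[[nm]]
      a[[nm]] <- if (is.function(f)) f(t) else as.numeric(f)
    }
    arows[i, ] <- a
    frames[[i]] <- forward_kinematics(a, dims, config$pelvis_trajectory(t),
                                      frame_index = i - 1L, timestamp = t)
  }
  adf <- data.frame(frame = seq_len(config$n_frames) - 1L,
                    timestamp = (seq_len(config$n_frames) - 1) / config$frame_rate,
                    arows)
  structure(list(clean = skeleton_sequence(frames, config$frame_rate),
                 angles = adf, dims = dims, config = config),
            class = "skel_motion")
}

#' @export
print.skel_motion <- function(x, ...) {
  cat(sprintf("synthetic motion: %d frames at %g Hz (clean ground truth)\n",
              length(x$clean$frames), x$clean$frame_rate))
  invisible(x)
}

#' Corrupt a clean sequence with tracker noise and dropout
#'
#' Applies the emulated failure modes of RGB-D skeleton trackers to a clean
#' sequence: zero-mean Gaussian perturbation with a large depth (z) standard
#' deviation and a small x,y one, independent per joint per frame; i.i.d.
#' per-joint dropout to the `(0,0,0)` missing sentinel; and optional
#' whole-frame loss bursts. Deterministic given `config$seed`.
#'
#' @param clean a `skel_sequence` with empty missing sets.
#' @param config a [motion_config()].
#' @return A `skel_sequence`; the injected dropout mask (frames x joints) is
#'   attached as attribute `"dropout"`.
#' @export
corrupt_sequence <- function(clean, config) {
  if (any(vapply(clean$frames, function(f) any(f$missing), TRUE)))
    .stopf("corrupt_sequence expects a clean sequence (no missing joints)")
  n <- length(clean$frames)
  set.seed(.derive_seed(config$seed, 1L))
  nx <- matrix(stats::rnorm(n * 18L, 0, config$xy_noise_sd), n, 18L)
  ny <- matrix(stats::rnorm(n * 18L, 0, config$xy_noise_sd), n, 18L)
  nz <- matrix(stats::rnorm(n * 18L, 0, config$depth_noise_sd), n, 18L)
  drop <- matrix(stats::runif(n * 18L) < config$dropout_prob, n, 18L)
  for (b in config$burst_at) {
    idx <- b:(b + max(config$burst_len - 1L, 0L))
    idx <- idx[idx >= 1L & idx <= n]
    drop[idx, ] <- TRUE
  }
  frames <- vector("list", n)
  for (i in seq_len(n)) {
    f <- clean$frames[[i]]
    p <- f$positions
    p[, 1L] <- p[, 1L] + nx[i, ]
    p[, 2L] <- p[, 2L] + ny[i, ]
    p[, 3L] <- p[, 3L] + nz[i, ]
    p[drop[i, ], ] <- 0
    frames[[i]] <- skeleton_frame(p, f$frame_index, f$timestamp,
                                  missing = drop[i, ])
  }
  out <- skeleton_sequence(frames, clean$frame_rate)
  attr(out, "dropout") <- drop
  out
}

# uniform sample inside a capsule around segment [p0, p1] (exact: cylinder
# body plus the two hemispherical caps, chosen by volume)
.sample_capsule <- function(n, p0, p1, r) {
  axis <- p1 - p0
  len <- .vnorm(axis)
  if (r <= 0) {
    if (len < 1e-12) return(matrix(rep(p0, each = n), n, 3L))
    s <- stats::runif(n, 0, len)
    return(rep(p0, each = n) + outer(s, axis / len))
  }
  ah <- if (len > 1e-12) axis / len else c(0, 0, 1)
  # orthonormal basis perpendicular to the axis
  ref <- if (abs(ah[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  b1 <- .vunit(.vcross(ah, ref)); b2 <- .vcross(ah, b1)
  vcyl <- pi * r^2 * len
  vsph <- 4 / 3 * pi * r^3
  incyl <- stats::runif(n) < vcyl / (vcyl + vsph)
  out <- matrix(0, n, 3L)
  ncy <- sum(incyl)
  if (ncy) {
    s <- stats::runif(ncy, 0, len)
    rho <- r * sqrt(stats::runif(ncy))
    phi <- stats::runif(ncy, 0, 2 * pi)
    out[incyl, ] <- rep(p0, each = ncy) + outer(s, ah) +
      outer(rho * cos(phi), b1) + outer(rho * sin(phi), b2)
  }
  nsp <- n - ncy
  if (nsp) {
    w <- matrix(stats::rnorm(nsp * 3L), nsp, 3L)
    w <- w / sqrt(rowSums(w^2)) * r * stats::runif(nsp)^(1 / 3)
    axial <- w %*% ah
    ends <- ifelse(axial >= 0, 1, 0)   # outward halves attach to each end
    ctr <- rep(p0, each = nsp) + outer(as.numeric(ends) * len, ah)
    out[!incyl, ] <- ctr + w
  }
  out
}

#' Sample per-limb capsule point clouds for a frame
#'
#' Emulates the segmented point clouds a depth sensor yields around the
#' subject's limbs: for each of the 17 limbs, `cloud_points_per_limb` points
#' uniform within a capsule of radius `cloud_radius` around the limb segment.
#' Clouds are sampled from the clean (true) pose — the body is visible to the
#' depth sensor even when the tracker drops a joint. Deterministic given
#' `config$seed` and the frame index.
#'
#' @param frame a clean `skel_frame`.
#' @param config a [motion_config()].
#' @param topo skeleton topology.
#' @return Named list (by child joint id, "1".."17") of `pc_segment`s.
#' @export
sample_point_clouds <- function(frame, config = motion_config(),
                                topo = skeleton_topology(validate = FALSE)) {
  if (any(frame$missing))
    .stopf("point clouds are sampled from the clean pose (no missing joints)")
  out <- vector("list", 17L)
  names(out) <- as.character(1:17)
  for (k in 1:17) {
    pid <- .parent_of(topo, k)
    set.seed(.derive_seed(config$seed, frame$frame_index * 64L + k))
    pts <- .sample_capsule(config$cloud_points_per_limb,
                           .pos(frame, pid), .pos(frame, k),
                           config$cloud_radius)
    out[[as.character(k)]] <- point_cloud_segment(pts, label = k)
  }
  out
}
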