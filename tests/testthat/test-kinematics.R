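test_that("plane projection behaves on in-plane, parallel and random input", {
  expect_equal(project_onto_plane(c(1, 1, 0), c(0, 0, 1)), c(1, 1, 0))
  expect_equal(project_onto_plane(c(0, 0, 5), c(0, 0, 1)), c(0, 0, 0))
  expect_error(project_onto_plane(c(1, 0, 0), c(0, 0, 0)), "zero")
  set.seed(1)
  for (k in 1:50) {
    v <- rnorm(3); n <- rnorm(3)
    r <- project_onto_plane(v, n)
    nh <- n / sqrt(sum(n^2))
    expect_lt(abs(sum(r * nh)), 1e-12 * sqrt(sum(v^2)))
    expect_equal(r + sum(v * nh) * nh, v, tolerance = 1e-12)
  }
})

test_that("angle_between is exact on collinear input and never NaN", {
  expect_identical(angle_between(c(1, 0, 0), c(0, 1, 0)), 90)
  expect_identical(angle_between(c(1, 0, 0), c(-1, 0, 0)), 180)
  expect_identical(angle_between(c(2, 0, 0), c(5, 0, 0)), 0)
  # near-parallel unit vectors whose dot exceeds 1 by round-off
  u <- c(1, 1e-8, 0); v <- c(1, 1e-8, 0)
  expect_false(is.nan(angle_between(u, v)))
  expect_lt(angle_between(u, v), 1e-6)
  expect_error(angle_between(c(0, 0, 0), c(1, 0, 0)), "zero")
})

test_that("betweenness matches the 2D sign-test oracle", {
  expect_true(lies_between(c(1, 1, 0), c(1, 0, 0), c(0, 1, 0)))
  expect_false(lies_between(c(-1, 1, 0), c(1, 0, 0), c(0, 1, 0)))
  expect_error(lies_between(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0)),
               "coplanar")
  set.seed(2)
  for (k in 1:1000) {
    a <- rnorm(3); b <- rnorm(3)
    # random coplanar v
    v <- runif(1, -2, 2) * a + runif(1, -2, 2) * b
    if (sqrt(sum(v^2)) < 1e-6) next
    expect_identical(lies_between(v, a, b), oracle_between(v, a, b))
  }
})

test_that("projection and angle helpers agree with brute force", {
  set.seed(3)
  worst_p <- 0; worst_a <- 0
  for (k in 1:2000) {
    v <- rnorm(3); n <- rnorm(3); u <- rnorm(3)
    worst_p <- max(worst_p,
                   max(abs(project_onto_plane(v, n) - oracle_project(v, n))))
    worst_a <- max(worst_a, abs(angle_between(u, v) - oracle_angle(u, v)))
  }
  expect_lt(worst_p, 1e-9)
  expect_lt(worst_a, 1e-9)
})

test_that("elbow and knee angles are the classic flexion angles", {
  pos <- forward_kinematics(default_pose_angles())$positions
  pos[3L, ] <- c(0, -0.3, 1); pos[4L, ] <- c(0, 0, 1); pos[5L, ] <- c(0, 0.3, 1)
  fr <- skeleton_frame(pos, missing = rep(FALSE, 18L))
  expect_identical(elbow_angle(fr, "right"), 180)     # exactly collinear
  pos[5L, ] <- c(0.3, 0, 1)
  fr <- skeleton_frame(pos, missing = rep(FALSE, 18L))
  expect_equal(elbow_angle(fr, "right"), 90, tolerance = 1e-12)
  # mirror symmetry: a left-right mirrored pose keeps the flexion angles
  a <- rand_angle_set()
  mir <- a
  rn <- grepl("right", ANGLE_NAMES); ln <- grepl("left", ANGLE_NAMES)
  mir[ANGLE_NAMES[rn]] <- a[sub("right", "left", ANGLE_NAMES[rn])]
  mir[ANGLE_NAMES[ln]] <- a[sub("left", "right", ANGLE_NAMES[ln])]
  f1 <- forward_kinematics(a); f2 <- forward_kinematics(mir)
  expect_equal(elbow_angle(f1, "right"), elbow_angle(f2, "left"),
               tolerance = 1e-9)
  expect_equal(knee_angle(f1, "left"), knee_angle(f2, "right"),
               tolerance = 1e-9)
})

test_that("T-pose and standing pose give the expected abduction angles", {
  a <- default_pose_angles()
  a[c("shoulder_right_y", "shoulder_right_z", "shoulder_right_x")] <- c(0, 0, 0)
  a[c("shoulder_left_y", "shoulder_left_z", "shoulder_left_x")] <- c(0, 0, 0)
  tp <- forward_kinematics(a)
  expect_equal(shoulder_angles(tp, "right")[["y"]], 0, tolerance = 1e-9)
  expect_equal(shoulder_angles(tp, "left")[["y"]], 0, tolerance = 1e-9)
  st <- forward_kinematics(default_pose_angles())
  expect_equal(abs(shoulder_angles(st, "right")[["y"]]), 90, tolerance = 1e-9)
})

test_that("spine angles measure axial twist and forward bend on constructed poses", {
  # hand-built pose, independent of the forward kinematics: hips level along
  # x, shoulders rotated 45 degrees about the vertical, upright torso
  base <- forward_kinematics(default_pose_angles())$positions
  p <- base
  pelvis <- (base[9L, ] + base[12L, ]) / 2
  p[9L, ] <- pelvis + c(-0.15, 0, 0); p[12L, ] <- pelvis + c(0.15, 0, 0)
  chest <- pelvis + c(0, -0.45, 0)
  p[2L, ] <- chest
  shdir <- c(cos(pi / 4), 0, -sin(pi / 4))  # rotated toward -z (forward)
  p[3L, ] <- chest - 0.18 * shdir           # right shoulder
  p[6L, ] <- chest + 0.18 * shdir           # left shoulder
  fr <- skeleton_frame(p, missing = rep(FALSE, 18L))
  sp <- spine_angles(fr)
  expect_equal(sp[["x"]], 45, tolerance = 1e-9)
  expect_equal(sp[["z"]], 0, tolerance = 1e-9)
  # forward bend of 30 degrees in the sagittal plane, untwisted
  p2 <- base
  p2[9L, ] <- pelvis + c(-0.15, 0, 0); p2[12L, ] <- pelvis + c(0.15, 0, 0)
  chest2 <- pelvis + 0.45 * c(0, -cos(pi / 6), -sin(pi / 6))
  p2[2L, ] <- chest2
  p2[3L, ] <- chest2 + c(-0.18, 0, 0); p2[6L, ] <- chest2 + c(0.18, 0, 0)
  fr2 <- skeleton_frame(p2, missing = rep(FALSE, 18L))
  expect_equal(spine_angles(fr2)[["z"]], 30, tolerance = 1e-9)
  expect_equal(spine_angles(fr2)[["x"]], 0, tolerance = 1e-9)
})

test_that("hip x-angle vanishes when the shank bends toward the rear", {
  # slight backward knee bend in the sagittal plane: the projected shank
  # aligns with the backwards-facing reference
  a <- default_pose_angles()
  a[c("hip_right_y", "hip_right_z", "hip_right_x")] <- c(-90, NA, 0)
  a["knee_right"] <- 170
  fr <- forward_kinematics(a)
  expect_equal(hip_angles(fr, "right")[["x"]], 0, tolerance = 1e-9)
})

test_that("negating the circumduction flips only the shoulder x-angle", {
  set.seed(8)
  a <- rand_angle_set()
  b <- a
  b["shoulder_right_x"] <- -a["shoulder_right_x"]
  r1 <- extract_all_angles(forward_kinematics(a))
  r2 <- extract_all_angles(forward_kinematics(b))
  expect_equal(r2[["shoulder_right_x"]], -r1[["shoulder_right_x"]],
               tolerance = 1e-9)
  keep <- setdiff(ANGLE_NAMES, "shoulder_right_x")
  expect_lt(max(abs(r2[keep] - r1[keep])), 1e-9)
})

test_that("angles are invariant under the rigid transforms that preserve them", {
  set.seed(9)
  a <- rand_angle_set()
  fr <- forward_kinematics(a)
  ref <- extract_all_angles(fr)
  body <- ANGLE_NAMES[grepl("shoulder|elbow|knee", ANGLE_NAMES)]
  for (k in 1:25) {
    R <- rot_axis(rnorm(3), runif(1, -180, 180))
    t <- rnorm(3)
    got <- extract_all_angles(transform_frame(fr, R, t))
    # body-relative angles survive any rigid transform
    expect_lt(max(abs(got[body] - ref[body])), 1e-7)
  }
  for (k in 1:25) {
    # hip and spine constructions reference global up: rotations about the
    # vertical plus translations
    R <- rot_axis(c(0, -1, 0), runif(1, -180, 180))
    got <- extract_all_angles(transform_frame(fr, R, rnorm(3)))
    expect_lt(max(abs(got - ref)), 1e-7)
  }
})

test_that("angle extraction is local: a missing wrist only kills the elbow and twist", {
  fr <- forward_kinematics(rand_angle_set())
  p <- fr$positions
  p[5L, ] <- 0   # right wrist (joint 4) dropped
  fr2 <- skeleton_frame(p)
  ja <- joint_angles(skeleton_sequence(list(fr2)))
  row <- ja$angles[1L, ]
  expect_true(is.na(row$elbow_right))
  expect_true(is.na(row$shoulder_right_x))  # twist needs the forearm
  defined <- setdiff(ANGLE_NAMES, c("elbow_right", "shoulder_right_x"))
  expect_false(anyNA(row[defined]))
})

test_that("angle CSV round trip preserves values and undefined flags", {
  mc <- motion_config(n_frames = 6, seed = 12, dropout_prob = 0)
  gt <- generate_motion(mc)
  seqc <- gt$clean
  p <- seqc$frames[[3L]]$positions
  p[5L, ] <- 0
  seqc$frames[[3L]] <- skeleton_frame(p, seqc$frames[[3L]]$frame_index,
                                      seqc$frames[[3L]]$timestamp)
  ja <- joint_angles(seqc)
  path <- withr::local_tempfile(fileext = ".csv")
  write_angles(ja, path)
  back <- read_angles(path)
  expect_equal(back$angles[, ANGLE_NAMES], ja$angles[, ANGLE_NAMES],
               tolerance = 1e-12, ignore_attr = TRUE)
})
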