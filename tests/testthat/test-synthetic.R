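test_that("the default standing pose has hanging arms and straight limbs", {
  fr <- forward_kinematics(default_pose_angles())
  expect_equal(abs(shoulder_angles(fr, "right")[["y"]]), 90, tolerance = 1e-9)
  expect_equal(abs(shoulder_angles(fr, "left")[["y"]]), 90, tolerance = 1e-9)
  expect_equal(elbow_angle(fr, "right"), 180, tolerance = 1e-6)
  expect_equal(knee_angle(fr, "left"), 180, tolerance = 1e-6)
  # straight leg: thigh and shank vectors antiparallel
  topo <- skeleton_topology()
  t1 <- limb_vector(fr, 9L, topo); t2 <- limb_vector(fr, 10L, topo)
  expect_equal(angle_between(-t1, t2), 180, tolerance = 1e-6)
})

test_that("generated frames reproduce the configured limb lengths exactly", {
  dims <- body_dimensions(upper_arm = 0.26, thigh = 0.44)
  topo <- skeleton_topology()
  set.seed(2)
  for (k in 1:10) {
    fr <- forward_kinematics(rand_angle_set(), dims)
    ll <- vapply(1:17, function(j) sqrt(sum(limb_vector(fr, j, topo)^2)), 0)
    expect_equal(ll, unname(dims$limb_lengths), tolerance = 1e-12)
  }
})

test_that("forward kinematics inverts the angle extraction", {
  set.seed(7)
  for (k in 1:100) {
    a <- rand_angle_set()
    rec <- extract_all_angles(forward_kinematics(a))
    expect_false(anyNA(rec))
    expect_lt(max(abs(rec - a)), 1e-6)
  }
  # targeted round trips from the constructed examples
  a <- rand_angle_set()
  a["elbow_right"] <- 90
  expect_equal(elbow_angle(forward_kinematics(a), "right"), 90,
               tolerance = 1e-9)
  a["knee_left"] <- 150
  expect_equal(knee_angle(forward_kinematics(a), "left"), 150,
               tolerance = 1e-9)
})

test_that("generate_motion is deterministic and follows its trajectories", {
  mc <- motion_config(n_frames = 30, seed = 5,
                      angle_trajectories = list(
                        elbow_right = function(t) 135 + 45 * sin(2 * pi * 0.5 * t)))
  g1 <- generate_motion(mc)
  g2 <- generate_motion(mc)
  expect_identical(g1$angles, g2$angles)
  expect_identical(g1$clean$frames[[17L]]$positions,
                   g2$clean$frames[[17L]]$positions)
  # extracted elbow series matches the input sinusoid
  tvec <- g1$angles$timestamp
  want <- 135 + 45 * sin(2 * pi * 0.5 * tvec)
  got <- vapply(g1$clean$frames, elbow_angle, 0, side = "right")
  expect_lt(max(abs(got - want)), 1e-6)
  # constant trajectories freeze the pose
  mcc <- motion_config(n_frames = 5, angle_trajectories = lapply(
    stats::setNames(ANGLE_NAMES, ANGLE_NAMES), function(nm) {
      v <- rand_angle_set()[[nm]]; function(t) v
    }))
  gc <- generate_motion(mcc)
  for (i in 2:5)
    expect_identical(gc$clean$frames[[i]]$positions,
                     gc$clean$frames[[1L]]$positions)
})

test_that("corruption matches its configured noise model", {
  mc0 <- motion_config(n_frames = 8, depth_noise_sd = 0, xy_noise_sd = 0,
                       dropout_prob = 0, seed = 1)
  gt <- generate_motion(mc0)
  same <- corrupt_sequence(gt$clean, mc0)
  for (i in 1:8)
    expect_identical(same$frames[[i]]$positions, gt$clean$frames[[i]]$positions)

  mc1 <- motion_config(n_frames = 4, dropout_prob = 1, seed = 1)
  gt1 <- generate_motion(mc1)
  allmiss <- corrupt_sequence(gt1$clean, mc1)
  expect_true(all(vapply(allmiss$frames, function(f) all(f$missing), TRUE)))

  # static pose, 1000 frames: sample sd of z within 10% of the nominal sd,
  # and the mean perturbation unbiased within 3 sd / sqrt(n)
  mc2 <- motion_config(n_frames = 1000, frame_rate = 30, seed = 9,
                       depth_noise_sd = 0.05, xy_noise_sd = 0.005,
                       dropout_prob = 0,
                       angle_trajectories = list(spine_z = function(t) 10))
  gt2 <- generate_motion(mc2)
  co2 <- corrupt_sequence(gt2$clean, mc2)
  zs <- vapply(co2$frames, function(f) f$positions[5L, 3L], 0)
  zt <- vapply(gt2$clean$frames, function(f) f$positions[5L, 3L], 0)
  expect_gt(stats::sd(zs - zt), 0.045)
  expect_lt(stats::sd(zs - zt), 0.055)
  xs <- vapply(co2$frames, function(f) f$positions[5L, 1L], 0)
  xt <- vapply(gt2$clean$frames, function(f) f$positions[5L, 1L], 0)
  expect_lt(abs(mean(xs - xt)), 3 * 0.005 / sqrt(1000))
  # identical seeds give identical corruption
  co2b <- corrupt_sequence(gt2$clean, mc2)
  expect_identical(co2$frames[[500L]]$positions, co2b$frames[[500L]]$positions)
})

test_that("burst dropout wipes whole frames", {
  mc <- motion_config(n_frames = 10, dropout_prob = 0, burst_at = 4L,
                      burst_len = 2L, seed = 2)
  gt <- generate_motion(mc)
  co <- corrupt_sequence(gt$clean, mc)
  expect_true(all(co$frames[[4L]]$missing))
  expect_true(all(co$frames[[5L]]$missing))
  expect_false(any(co$frames[[6L]]$missing))
})

test_that("capsule clouds hug their limb segments", {
  fr <- forward_kinematics(default_pose_angles())
  topo <- skeleton_topology()
  seg_dist <- function(p, a, b) {
    ab <- b - a
    t <- max(0, min(1, sum((p - a) * ab) / sum(ab^2)))
    sqrt(sum((a + t * ab - p)^2))
  }
  mc <- motion_config(cloud_points_per_limb = 500L, cloud_radius = 0.04,
                      seed = 3)
  cl <- sample_point_clouds(fr, mc)
  for (j in c(4L, 9L, 1L)) {
    pid <- topo$joints$parent_id[j + 1L]
    a <- fr$positions[pid + 1L, ]; b <- fr$positions[j + 1L, ]
    d <- apply(cl[[as.character(j)]]$points, 1L, seg_dist, a = a, b = b)
    expect_lte(max(d), 0.04 + 1e-12)
    # nearest cloud point to the true child joint lies within the radius
    dchild <- sqrt(rowSums(sweep(cl[[as.character(j)]]$points, 2L, b)^2))
    expect_lte(min(dchild), 0.04)
  }
  # zero radius degenerates to points exactly on the segments
  mc0 <- motion_config(cloud_points_per_limb = 50L, cloud_radius = 0,
                       seed = 3)
  cl0 <- sample_point_clouds(fr, mc0)
  a <- fr$positions[3L, ]; b <- fr$positions[4L, ]  # shoulder -> elbow
  d0 <- apply(cl0[["3"]]$points, 1L, seg_dist, a = a, b = b)
  expect_lt(max(d0), 1e-12)
  # determinism
  cl2 <- sample_point_clouds(fr, mc)
  expect_identical(cl[["7"]]$points, cl2[["7"]]$points)
})
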