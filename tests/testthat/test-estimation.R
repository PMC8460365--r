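test_that("the reference frame minimizes the depth standard deviation", {
  # three static frames with injected z spreads 0.08 / 0.01 / 0.05
  base <- forward_kinematics(default_pose_angles())
  spread <- function(fr, s, i) {
    p <- fr$positions
    set.seed(100 + i)
    p[, 3L] <- mean(p[, 3L]) + s * scale(rnorm(18))[, 1L]
    skeleton_frame(p, frame_index = i, timestamp = i / 30)
  }
  frames <- list(spread(base, 0.08, 0L), spread(base, 0.01, 1L),
                 spread(base, 0.05, 2L))
  s <- skeleton_sequence(frames)
  expect_identical(select_reference_frame(s, 3L), 1L)
  # an exact tie (identical poses) resolves to the earliest frame
  f0 <- spread(base, 0.05, 0L)
  f1 <- skeleton_frame(f0$positions, 1L, 1 / 30)
  tie <- skeleton_sequence(list(f0, f1))
  expect_identical(select_reference_frame(tie, 2L), 0L)
  # frames with missing joints are excluded even if their z-sd is lowest
  p <- frames[[2L]]$positions; p[4L, ] <- 0
  frames[[2L]] <- skeleton_frame(p, 1L, 1 / 30)
  expect_identical(select_reference_frame(skeleton_sequence(frames), 3L), 2L)
  # nothing fully observed: initialization error
  allmiss <- lapply(0:2, function(i) {
    p <- base$positions; p[3L, ] <- 0
    skeleton_frame(p, i, i / 30)
  })
  expect_error(select_reference_frame(skeleton_sequence(allmiss), 3L),
               "initialization|fully observed")
})

test_that("reference selection equals brute force on a 50-frame capture", {
  mc <- motion_config(n_frames = 50, seed = 21, dropout_prob = 0.05)
  gt <- generate_motion(mc)
  corr <- corrupt_sequence(gt$clean, mc)
  # inject one zero-noise frame (a pristine capture of the pose)
  corr$frames[[37L]] <- gt$clean$frames[[37L]]
  brute <- function(s) {
    zsd <- vapply(s$frames, function(f)
      if (any(f$missing)) Inf else stats::sd(f$positions[, 3L]), 0)
    s$frames[[which.min(zsd)]]$frame_index
  }
  expect_identical(select_reference_frame(corr, 50L), brute(corr))
})

test_that("limb distances come out of the reference frame construction", {
  dims <- body_dimensions()
  fr <- forward_kinematics(default_pose_angles(), dims)
  lt <- compute_limb_distances(fr)
  expect_identical(nrow(lt), 17L)
  expect_equal(lt$distance, unname(dims$limb_lengths), tolerance = 1e-12)
  # elementary case: child one meter above its parent
  p <- fr$positions
  p[10L, ] <- p[9L, ] + c(0, 0, 1)    # right knee 1 m from right hip in z
  lt2 <- compute_limb_distances(skeleton_frame(p, missing = rep(FALSE, 18L)))
  expect_equal(lt2$distance[lt2$child_id == 9L], 1.0, tolerance = 1e-12)
  # missing joint forbids the computation
  p[4L, ] <- 0
  expect_error(compute_limb_distances(skeleton_frame(p)), "missing")
})

test_that("joint validation combines displacement and limb-interval checks", {
  params <- estimation_params()
  prev <- c(0, 0, 2); parent <- c(0, -0.3, 2)
  expect_false(validate_joint(NULL, prev, 0.3, parent, params))     # missing
  expect_true(validate_joint(prev, prev, 0.3, parent, params))      # at rest
  # limb 0.30, bounds [0.8, 1.2], child 0.45 from parent: reject
  expect_false(validate_joint(parent + c(0, 0.45, 0), prev + c(0, 0.15, 0),
                              0.3, parent, params))
  # displacement above the cap: reject even with a perfect limb length
  expect_false(validate_joint(prev + c(0.3, 0, 0), prev, 0.3,
                              parent + c(0.3, 0, 0), params))
})

test_that("repair picks the nearest limb-consistent cloud point", {
  params <- estimation_params()
  parent <- c(0, 0, 2); truth <- parent + c(0, 0.3, 0)
  prev <- truth + c(0.01, 0, 0)
  # singleton cloud at the true location
  r <- repair_joint(prev, NULL, parent, 0.3, rbind(truth), params)
  expect_identical(r$action, "repaired")
  expect_equal(r$position, truth)
  # depth outlier: current has good x,y but z off by 0.5 m
  cloud <- rbind(truth + c(0.2, 0.2, 0.2),      # violates the limb interval
                 truth)
  cur <- truth + c(0, 0, 0.5)
  r2 <- repair_joint(prev, cur, parent, 0.3, cloud, params)
  expect_identical(r2$action, "repaired")
  expect_lt(abs(r2$position[3L] - truth[3L]), 0.5)
  dl <- sqrt(sum((r2$position - parent)^2))
  expect_gte(dl, 0.8 * 0.3); expect_lte(dl, 1.2 * 0.3)
  # no qualifying cloud point: previous position carried forward, flagged
  far <- rbind(parent + c(0, 2, 0))
  r3 <- repair_joint(prev, NULL, parent, 0.3, far, params)
  expect_identical(r3$action, "fallback")
  expect_equal(r3$position, prev)
  # mean-update: candidate within the bound of the current observation
  cur4 <- truth + c(0.02, 0, 0)
  r4 <- repair_joint(prev, cur4, parent, 0.3, rbind(truth), params)
  expect_equal(r4$position, (truth + cur4) / 2)
})

test_that("a clean noiseless sequence passes through unchanged", {
  mc <- motion_config(n_frames = 20, seed = 2, depth_noise_sd = 0,
                      xy_noise_sd = 0, dropout_prob = 0)
  gt <- generate_motion(mc)
  clouds <- lapply(gt$clean$frames, sample_point_clouds, config = mc)
  fit <- skeleton_repair(gt$clean, clouds)
  ref <- fit$reference_frame
  expect_true(all(fit$log$action[fit$log$frame > ref] == "kept"))
  for (f in fit$sequence$frames)
    expect_identical(f$positions, gt$clean$frames[[f$frame_index + 1L]]$positions)
  # idempotence: repairing the repaired output changes nothing
  fit2 <- skeleton_repair(fit$sequence, clouds[vapply(fit$sequence$frames,
                                                      `[[`, 0L, "frame_index") + 1L])
  for (f in fit2$sequence$frames)
    expect_identical(f$positions,
                     fit$sequence$frames[[which(vapply(fit$sequence$frames, `[[`, 0L,
                                                       "frame_index") == f$frame_index)]]$positions)
})

test_that("depth noise on one wrist is damped by the repair", {
  mc <- motion_config(n_frames = 80, seed = 31, depth_noise_sd = 0,
                      xy_noise_sd = 0, dropout_prob = 0)
  gt <- generate_motion(mc)
  corr <- gt$clean
  set.seed(77)
  for (i in seq_along(corr$frames)) {
    p <- corr$frames[[i]]$positions
    p[5L, 3L] <- p[5L, 3L] + rnorm(1, 0, 0.05)   # right wrist depth noise
    corr$frames[[i]] <- skeleton_frame(p, corr$frames[[i]]$frame_index,
                                       corr$frames[[i]]$timestamp)
  }
  clouds <- lapply(gt$clean$frames, sample_point_clouds, config = mc)
  fit <- skeleton_repair(corr, clouds)
  idx <- vapply(fit$sequence$frames, `[[`, 0L, "frame_index")
  zerr <- function(frames) mean(abs(vapply(frames, function(f)
    f$positions[5L, 3L], 0) -
      vapply(gt$clean$frames[idx + 1L], function(f) f$positions[5L, 3L], 0)))
  expect_lt(zerr(fit$sequence$frames), zerr(corr$frames[idx + 1L]))
})

test_that("whole-frame dropout is reconstructed from the clouds", {
  mc <- motion_config(n_frames = 30, seed = 41, depth_noise_sd = 0,
                      xy_noise_sd = 0, dropout_prob = 0, burst_at = 20L,
                      burst_len = 2L)
  gt <- generate_motion(mc)
  corr <- corrupt_sequence(gt$clean, mc)
  clouds <- lapply(gt$clean$frames, sample_point_clouds, config = mc)
  fit <- skeleton_repair(corr, clouds)
  out <- fit$sequence$frames
  idx <- vapply(out, `[[`, 0L, "frame_index")
  for (fi in c(19L, 20L)) {            # frame_index of the burst frames
    f <- out[[which(idx == fi)]]
    expect_false(any(f$missing))
    acts <- fit$log$action[fit$log$frame == fi]
    expect_true(all(acts %in% c("repaired", "fallback")))
    # repaired joints honor the limb interval against their parent
    lg <- fit$log[fit$log$frame == fi, ]
    topo <- skeleton_topology()
    for (j in 1:17) {
      if (lg$action[lg$joint_id == j] != "repaired") next
      pid <- topo$joints$parent_id[j + 1L]
      dl <- sqrt(sum((f$positions[j + 1L, ] - f$positions[pid + 1L, ])^2))
      L <- fit$limb_table$distance[fit$limb_table$child_id == j]
      expect_gte(dl, 0.8 * L - 1e-9)
      expect_lte(dl, 1.2 * L + 1e-9)
    }
    # and land near the true pose (cloud radius + capture tolerance)
    tru <- gt$clean$frames[[fi + 1L]]$positions
    rep_j <- lg$joint_id[lg$action == "repaired"]
    err <- sqrt(rowSums((f$positions[rep_j + 1L, , drop = FALSE] -
                           tru[rep_j + 1L, , drop = FALSE])^2))
    expect_lt(max(err), 0.15)
  }
})

test_that("repair reduces the mean 3D error under the emulated conditions", {
  res <- lapply(c(61L, 62L, 63L), repair_replicate, n_frames = 120L)
  for (r in res) expect_lt(r$after, r$before)
})
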